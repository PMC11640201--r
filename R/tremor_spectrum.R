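#' Fit the line-of-best-fit smoothing spline to an unwrapped trace
#'
#' Fits a cubic smoothing spline of distance against unwrapped angle whose
#' residual sum of squares is driven to the target \eqn{s = n \times N},
#' where \eqn{n} is the number of trace points and \eqn{N} the smoothing
#' scale factor. The spline is the idealized, tremor-free spiral path: with
#' `N = 0` it interpolates the data (zero deviation at every point); larger
#' `N` yields a smoother curve and hence a larger tremor residual. When even
#' the maximally smoothed fit (a straight line — the ideal Archimedean
#' profile) has residual sum of squares below the target, that fit is
#' returned, mirroring the convention that the smoothest curve satisfying
#' the residual budget wins.
#'
#' Duplicate angles are collapsed by averaging before fitting, as smoothing
#' splines require increasing abscissae; the fit is evaluated back at every
#' original trace angle.
#'
#' @param trace A `polar_trace` from [unwrap_spiral()].
#' @param N Smoothing scale factor (default 10).
#' @return Numeric vector of smoothed distances, one per trace point, with
#'   attribute `s` (the residual target actually used).
#' @export
fit_lobf <- function(trace, N = 10) {
  stopifnot(inherits(trace, "polar_trace"))
  if (N < 0) stop("`N` must be >= 0", call. = FALSE)
  x <- trace$angles
  y <- trace$distances
  n <- trace$n_points
  if (n < 4) stop("too few points to fit a cubic spline", call. = FALSE)

  ux <- sort(unique(x))
  if (length(ux) < 4) stop("too few distinct angles to fit a cubic spline", call. = FALSE)
  s_target <- n * N

  if (N == 0) {
    uy <- vapply(ux, function(v) mean(y[x == v]), numeric(1))
    f <- stats::splinefun(ux, uy, method = "natural")
    out <- f(x)
    attr(out, "s") <- 0
    return(out)
  }

  # In the maximal-smoothing limit the cubic smoothing spline degenerates to
  # the least-squares straight line; if even that fit sits within the
  # residual budget, the line is the smoothest curve satisfying it.
  line_fit <- stats::lm.fit(cbind(1, x), y)
  rss_line <- sum(line_fit$residuals^2)
  if (s_target >= rss_line) {
    out <- as.numeric(cbind(1, x) %*% line_fit$coefficients)
    attr(out, "s") <- s_target
    return(out)
  }

  fit_at <- function(lambda) {
    tryCatch(stats::smooth.spline(x, y, lambda = lambda, keep.data = FALSE),
             error = function(e) NULL)
  }
  rss_of <- function(fit) sum((y - stats::predict(fit, x)$y)^2)

  lo <- -10
  hi <- 2
  fit_hi <- fit_at(10^hi)
  while (!is.null(fit_hi) && rss_of(fit_hi) < s_target && hi < 10) {
    hi <- hi + 1
    nxt <- fit_at(10^hi)
    if (is.null(nxt)) {
      hi <- hi - 1
      break
    }
    fit_hi <- nxt
  }
  fit_lo <- fit_at(10^lo)
  if (is.null(fit_hi) || is.null(fit_lo)) {
    stop("smoothing-spline fit failed", call. = FALSE)
  }
  fit <- if (rss_of(fit_hi) <= s_target) {
    fit_hi
  } else if (rss_of(fit_lo) >= s_target) {
    fit_lo
  } else {
    root <- stats::uniroot(
      function(lg) rss_of(fit_at(10^lg)) - s_target,
      lower = lo, upper = hi, tol = 0.005
    )
    fit_at(10^root$root)
  }
  out <- stats::predict(fit, x)$y
  attr(out, "s") <- s_target
  out
}

#' Tremor-deviation signal of a trace
#'
#' The tremor signal is the pointwise difference between the unwrapped
#' distances and the line of best fit. Trace points are treated as uniformly
#' spaced in time over the nominal drawing duration, giving a synthetic
#' sampling rate `fs = n_points / draw_duration`.
#'
#' @param trace A `polar_trace`.
#' @param lobf Smoothed distances from [fit_lobf()] (same length).
#' @param draw_duration Nominal drawing time in seconds (default 10).
#' @return An object of class `deviation_signal`: list with `amplitudes`
#'   (px), `angles` (radians) and `fs` (Hz).
#' @export
deviation_signal <- function(trace, lobf, draw_duration = 10) {
  stopifnot(inherits(trace, "polar_trace"))
  if (length(lobf) != trace$n_points) {
    stop("trace and LOBF lengths differ", call. = FALSE)
  }
  if (draw_duration <= 0) stop("`draw_duration` must be positive", call. = FALSE)
  structure(
    list(
      amplitudes = as.numeric(trace$distances - lobf),
      angles = trace$angles,
      fs = trace$n_points / draw_duration
    ),
    class = "deviation_signal"
  )
}

#' Normalized single-sided magnitude spectrum of the tremor signal
#'
#' Computes the FFT of the deviation amplitudes, normalizes the magnitudes by
#' the signal length, and keeps the first `floor(n/2)` bins (the positive
#' half; single-sided magnitudes are not doubled). Frequencies are
#' `k * fs / n` for bin index `k = 0, 1, ...`.
#'
#' @param dev A `deviation_signal`.
#' @return An object of class `tremor_spectrum`: list with `freqs` (Hz),
#'   `mags` (px) and `n_signal` (original signal length).
#' @export
to_spectrum <- function(dev) {
  stopifnot(inherits(dev, "deviation_signal"))
  x <- dev$amplitudes
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  mags <- Mod(stats::fft(x)) / n
  freqs <- (seq_len(n) - 1) * dev$fs / n
  half <- floor(n / 2)
  structure(
    list(freqs = freqs[seq_len(half)], mags = mags[seq_len(half)], n_signal = n),
    class = "tremor_spectrum"
  )
}

#' @export
print.tremor_spectrum <- function(x, ...) {
  k <- which.max(x$mags)
  cat(sprintf(
    "Tremor spectrum: %d bins (0-%.2f Hz), peak %.4f px at %.2f Hz\n",
    length(x$freqs), max(x$freqs), x$mags[k], x$freqs[k]))
  invisible(x)
}
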