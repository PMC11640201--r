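#' Noise threshold of a tremor spectrum
#'
#' Twice the mean of all magnitudes in the single-sided spectrum, rounded to
#' three decimal places. Bins strictly above the threshold are "signal", the
#' rest "noise".
#'
#' @param spectrum A `tremor_spectrum`.
#' @return Threshold in px.
#' @export
noise_threshold <- function(spectrum) {
  stopifnot(inherits(spectrum, "tremor_spectrum"))
  if (length(spectrum$mags) == 0) stop("empty spectrum", call. = FALSE)
  round(2 * mean(spectrum$mags), 3)
}

#' Signal-to-noise ratio of a tremor spectrum
#'
#' Splits the magnitude bins at the noise threshold and returns the ratio of
#' mean signal power to mean noise power, minus one:
#' \deqn{SNR = \frac{\sum s_i^2 / |s|}{\sum n_i^2 / |n|} - 1.}
#' With no bin above the threshold the SNR is undefined (`NaN`, later removed
#' by row cleaning); with zero noise power it is `Inf`.
#'
#' @param spectrum A `tremor_spectrum`.
#' @param threshold Noise threshold (px), from [noise_threshold()].
#' @return Dimensionless ratio.
#' @export
compute_snr <- function(spectrum, threshold) {
  stopifnot(inherits(spectrum, "tremor_spectrum"))
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  mags <- spectrum$mags
  sig <- mags[mags > threshold]
  noi <- mags[mags <= threshold]
  if (length(sig) == 0) return(NaN)
  sig_pow <- sum(sig^2) / length(sig)
  noi_pow <- if (length(noi) == 0) 0 else sum(noi^2) / length(noi)
  if (noi_pow == 0) return(Inf)
  sig_pow / noi_pow - 1
}

#' Five frequency-domain tremor features
#'
#' From the single-sided spectrum: the peak magnitude (maximum bin), the peak
#' frequency (frequency of that bin, lowest index on ties; the DC bin takes
#' part in the search), the SNR, the population variance of the
#' above-threshold magnitudes (0 for a single signal bin, `NaN` for none),
#' and the bandwidth (count of above-threshold bins).
#'
#' @param spectrum A `tremor_spectrum`.
#' @return Named list with `peak_magnitude`, `peak_frequency`, `snr`,
#'   `variance`, `bandwidth` and `noise_threshold`.
#' @export
extract_frequency_features <- function(spectrum) {
  stopifnot(inherits(spectrum, "tremor_spectrum"))
  mags <- spectrum$mags
  if (length(mags) == 0) stop("empty spectrum", call. = FALSE)
  thr <- noise_threshold(spectrum)
  k <- which.max(mags)  # lowest index on ties
  sig <- mags[mags > thr]
  list(
    peak_magnitude = mags[k],
    peak_frequency = spectrum$freqs[k],
    snr = compute_snr(spectrum, thr),
    variance = if (length(sig) == 0) NaN else mean((sig - mean(sig))^2),
    bandwidth = length(sig),
    noise_threshold = thr
  )
}
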