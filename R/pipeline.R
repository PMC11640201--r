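#' Full frequency-feature pipeline for one drawing
#'
#' Runs binarization, Zhang-Suen thinning, contour and centre detection,
#' spiral unwrapping, the smoothing-spline line of best fit, the tremor
#' deviation signal and its spectrum, and returns the five frequency
#' features. Drawings the pipeline cannot process (no foreground, junctions
#' from self-intersections, traces too short) yield `NaN` features rather
#' than errors when `quiet = TRUE`.
#'
#' @param image Grayscale matrix, intensities in \[0, 255\].
#' @param N Smoothing scale factor of the line of best fit (default 10).
#' @param draw_duration Nominal drawing time in seconds (default 10).
#' @param blur_kernel,block_size,offset_c Binarization parameters, see
#'   [binarize_spiral()].
#' @param quiet Return all-`NaN` features instead of erroring on unusable
#'   drawings (default `TRUE`).
#' @return Named list with `peak_magnitude`, `peak_frequency`, `snr`,
#'   `variance`, `bandwidth`.
#' @export
frequency_features_image <- function(image, N = 10, draw_duration = 10,
                                     blur_kernel = 5, block_size = 11,
                                     offset_c = 2, quiet = TRUE) {
  run <- function() {
    mask <- binarize_spiral(image, blur_kernel, block_size, offset_c)
    skel <- thin(mask)
    ctr <- find_center(largest_contour(mask))
    trace <- unwrap_spiral(skel, ctr)
    for (it in 1:2) {
      ctr2 <- refine_center(trace, ctr)
      if (max(abs(ctr2 - ctr)) < 0.25) break
      ctr <- ctr2
      trace <- unwrap_spiral(skel, ctr)
    }
    lobf <- fit_lobf(trace, N = N)
    dev <- deviation_signal(trace, lobf, draw_duration = draw_duration)
    f <- extract_frequency_features(to_spectrum(dev))
    f[c("peak_magnitude", "peak_frequency", "snr", "variance", "bandwidth")]
  }
  if (!quiet) return(run())
  tryCatch(run(), error = function(e) {
    list(peak_magnitude = NaN, peak_frequency = NaN, snr = NaN,
         variance = NaN, bandwidth = NaN)
  })
}

#' Full tremor analysis of one drawing
#'
#' Like [frequency_features_image()] but returns the intermediate objects
#' (mask, skeleton, centre, trace, deviation signal and spectrum) for
#' inspection and plotting.
#'
#' @inheritParams frequency_features_image
#' @return A list of class `spiral_analysis` with components `mask`,
#'   `skeleton`, `center`, `trace`, `lobf`, `deviation`, `spectrum`,
#'   `features`.
#' @export
analyze_spiral <- function(image, N = 10, draw_duration = 10,
                           blur_kernel = 5, block_size = 11, offset_c = 2) {
  mask <- binarize_spiral(image, blur_kernel, block_size, offset_c)
  skel <- thin(mask)
  ctr <- find_center(largest_contour(mask))
  trace <- unwrap_spiral(skel, ctr)
  for (it in 1:2) {
    ctr2 <- refine_center(trace, ctr)
    if (max(abs(ctr2 - ctr)) < 0.25) break
    ctr <- ctr2
    trace <- unwrap_spiral(skel, ctr)
  }
  lobf <- fit_lobf(trace, N = N)
  dev <- deviation_signal(trace, lobf, draw_duration = draw_duration)
  spec <- to_spectrum(dev)
  structure(
    list(mask = mask, skeleton = skel, center = ctr, trace = trace,
         lobf = lobf, deviation = dev, spectrum = spec,
         features = extract_frequency_features(spec)),
    class = "spiral_analysis"
  )
}

#' @export
print.spiral_analysis <- function(x, ...) {
  f <- x$features
  cat("Spiral tremor analysis\n")
  cat(sprintf("  trace: %d points, fs = %.1f Hz\n",
              x$trace$n_points, x$deviation$fs))
  cat(sprintf("  deviation RMS: %.3f px\n", sqrt(mean(x$deviation$amplitudes^2))))
  cat(sprintf("  peak %.4f px at %.2f Hz | SNR %.2f | variance %.5f | bandwidth %d bins\n",
              f$peak_magnitude, f$peak_frequency, f$snr, f$variance, f$bandwidth))
  invisible(x)
}

#' Plot a spiral tremor analysis
#'
#' Four panels: the binarized mask, the unwrapped angle-distance trace with
#' its line of best fit, the tremor deviation signal, and the single-sided
#' magnitude spectrum with the noise threshold.
#'
#' @param x A `spiral_analysis`.
#' @param ... Unused.
#' @export
plot.spiral_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$mask)[, nrow(x$mask):1], col = c("white", "black"),
                  axes = FALSE, main = "binarized drawing", useRaster = TRUE)
  plot(x$trace$angles, x$trace$distances, type = "l", col = "grey40",
       xlab = "angle (rad)", ylab = "distance (px)", main = "unwrapped trace + LOBF")
  graphics::lines(x$trace$angles, as.numeric(x$lobf), col = "red")
  plot(x$deviation$angles, x$deviation$amplitudes, type = "l",
       xlab = "angle (rad)", ylab = "deviation (px)", main = "tremor deviation")
  plot(x$spectrum$freqs, x$spectrum$mags, type = "h",
       xlab = "frequency (Hz)", ylab = "magnitude (px)", main = "spectrum")
  graphics::abline(h = x$features$noise_threshold, col = "orange")
  invisible(x)
}
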