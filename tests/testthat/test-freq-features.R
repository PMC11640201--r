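spectrum_of <- function(mags, freqs = seq_along(mags) - 1) {
  structure(list(freqs = freqs, mags = mags, n_signal = 2 * length(mags)),
            class = "tremor_spectrum")
}

# naive loop-based re-implementation of the five feature definitions,
# used as an independent oracle
oracle_features <- function(freqs, mags) {
  thr <- round(2 * (sum(mags) / length(mags)), 3)
  pk <- 1
  for (i in seq_along(mags)) if (mags[i] > mags[pk]) pk <- i
  sig <- c(); noi <- c()
  for (m in mags) if (m > thr) sig <- c(sig, m) else noi <- c(noi, m)
  snr <- if (length(sig) == 0) {
    NaN
  } else {
    sp <- 0; for (m in sig) sp <- sp + m^2
    np <- 0; for (m in noi) np <- np + m^2
    sp <- sp / length(sig)
    np <- if (length(noi) == 0) 0 else np / length(noi)
    if (np == 0) Inf else sp / np - 1
  }
  vr <- if (length(sig) == 0) {
    NaN
  } else {
    mu <- sum(sig) / length(sig)
    v <- 0; for (m in sig) v <- v + (m - mu)^2
    v / length(sig)
  }
  list(peak_magnitude = mags[pk], peak_frequency = freqs[pk], snr = snr,
       variance = vr, bandwidth = length(sig), noise_threshold = thr)
}

test_that("noise threshold is twice the spectrum mean, 3-decimal rounded", {
  expect_equal(noise_threshold(spectrum_of(c(1, 1, 10, 1, 1))), 5.6)
  expect_equal(noise_threshold(spectrum_of(rep(0, 8))), 0)
  expect_equal(noise_threshold(spectrum_of(c(0.3333, 0.3334))), 0.667)
})

test_that("SNR follows the mean-power ratio definition", {
  sp <- spectrum_of(c(1, 1, 10, 1, 1))
  expect_equal(compute_snr(sp, 5.6), 99)
  # all-equal magnitudes: nothing exceeds twice the mean
  spe <- spectrum_of(rep(2, 6))
  expect_true(is.nan(compute_snr(spe, noise_threshold(spe))))
  # zero noise power
  expect_equal(compute_snr(spectrum_of(c(0, 0, 4, 0)), 2), Inf)
})

test_that("the five features match hand-computed instances", {
  f <- extract_frequency_features(spectrum_of(c(1, 1, 10, 1, 1), 0:4))
  expect_equal(f$peak_magnitude, 10)
  expect_equal(f$peak_frequency, 2)
  expect_equal(f$noise_threshold, 5.6)
  expect_equal(f$bandwidth, 1)
  expect_equal(f$variance, 0)
  expect_equal(f$snr, 99)

  f2 <- extract_frequency_features(spectrum_of(c(0, 8, 0, 6, 0), 0:4))
  expect_equal(f2$noise_threshold, 5.6)
  expect_equal(f2$bandwidth, 2)
  expect_equal(f2$variance, 1)  # population variance of {8, 6}
  expect_equal(f2$peak_frequency, 1)

  # flat spectrum: no signal bins
  f3 <- extract_frequency_features(spectrum_of(rep(1, 10), 0:9))
  expect_equal(f3$bandwidth, 0)
  expect_true(is.nan(f3$variance))
  expect_true(is.nan(f3$snr))
})

test_that("features agree with the naive oracle on random spectra", {
  set.seed(11)
  same <- function(a, b) (is.nan(a) && is.nan(b)) || isTRUE(all.equal(a, b))
  for (i in 1:1000) {
    n <- sample(5:200, 1)
    mags <- switch(sample(3, 1),
                   abs(rnorm(n)),
                   rexp(n),
                   round(abs(rnorm(n)), sample(0:3, 1)))  # ties at threshold
    freqs <- (seq_len(n) - 1) * runif(1, 0.01, 1)
    got <- extract_frequency_features(spectrum_of(mags, freqs))
    want <- oracle_features(freqs, mags)
    for (nm in names(want)) {
      expect_true(same(got[[nm]], want[[nm]]),
                  label = sprintf("iteration %d, feature %s", i, nm))
    }
  }
})

test_that("features transform correctly under magnitude scaling", {
  set.seed(4)
  mags <- abs(rnorm(50))
  freqs <- 0:49
  base <- extract_frequency_features(spectrum_of(mags, freqs))
  for (cc in c(0.5, 3)) {
    sc <- extract_frequency_features(spectrum_of(cc * mags, freqs))
    expect_equal(sc$peak_magnitude, cc * base$peak_magnitude)
    expect_equal(sc$peak_frequency, base$peak_frequency)
    expect_equal(sc$bandwidth, base$bandwidth)
    expect_equal(sc$variance, cc^2 * base$variance, tolerance = 1e-2)
    expect_equal(sc$snr, base$snr, tolerance = 1e-2)
  }
})
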