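test_that("rotation augmentation covers -45 to 165 degrees in 15-degree steps", {
  img <- clean_spiral_image()
  rots <- augment_rotations(img)
  expect_length(rots, 15)
  expect_identical(rots[["0"]], img)          # 0 degrees: bit-identical
  expect_equal(rots[["45"]][1, 1], 255)       # exposed corner is white
  expect_true(all(vapply(rots, function(m) identical(dim(m), dim(img)),
                         logical(1))))
})

test_that("frequency features are rotation-invariant within pixel tolerance", {
  img <- cached("tremor_img",
                render_spiral(test_spec(seed = 31, tremor_amplitude = 4,
                                        tremor_frequency = 5)))
  f0 <- cached("tremor_f0", frequency_features_image(img))
  f90 <- frequency_features_image(rotate_image(img, 90))
  expect_equal(f90$peak_frequency, f0$peak_frequency, tolerance = 0.1)
  expect_equal(f90$peak_magnitude, f0$peak_magnitude, tolerance = 0.1)
  expect_equal(f90$snr, f0$snr, tolerance = 0.1)
})

test_that("feature tables have one record per image and NaN on failure", {
  imgs <- list(clean_spiral_image(),
               crossing_image(),
               render_spiral(test_spec(seed = 32)))
  tab <- build_feature_table(imgs, c("healthy", "parkinson", "healthy"),
                             feature_set = "F")
  expect_equal(nrow(tab), 3)
  expect_true(all(is.nan(unlist(tab[2, c("snr", "peak_frequency")]))))
  expect_false(anyNA(tab[c(1, 3), spiralpd:::feature_columns("F")]))

  tab_fp <- build_feature_table(imgs[c(1, 3)], c("healthy", "healthy"),
                                feature_set = "FP")
  expect_setequal(setdiff(names(tab_fp), c("id", "label")),
                  c("peak_magnitude", "peak_frequency", "snr", "variance",
                    "bandwidth", "thickness", "pressure"))

  tab2 <- build_feature_table(imgs, c("healthy", "parkinson", "healthy"),
                              feature_set = "F")
  expect_identical(tab, tab2)  # deterministic
})

test_that("cleaning drops NaN rows and errors when nothing is left", {
  tab <- blob_table(3, feature_set = "F")
  tab$snr[2] <- NaN
  expect_message(cl <- clean_table(tab), "removed 1")
  expect_equal(nrow(cl), 5)
  expect_equal(cl$id, tab$id[-2])

  expect_identical(nrow(clean_table(blob_table(3))), 6L)

  bad <- blob_table(2, feature_set = "P")
  bad$thickness <- NaN
  expect_error(suppressMessages(clean_table(bad)), "empty table after cleaning")
})

test_that("feature CSVs round-trip exactly, including NaN", {
  tab <- blob_table(4, feature_set = "FP")
  tab$snr[3] <- NaN
  tab$variance[5] <- Inf
  path <- tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  back <- read_feature_csv(path)
  expect_equal(attr(back, "feature_set"), "FP")
  expect_identical(back$id, tab$id)
  expect_identical(back$label, tab$label)
  for (cc in spiralpd:::feature_columns("FP")) {
    expect_equal(back[[cc]], tab[[cc]], tolerance = 1e-14)
  }
  expect_true(is.nan(back$snr[3]))
  expect_true(is.infinite(back$variance[5]))
})

test_that("subsetting a combined table preserves structure", {
  tab <- blob_table(5, feature_set = "FP")
  f <- subset_features(tab, "F")
  expect_equal(attr(f, "feature_set"), "F")
  expect_setequal(names(f), c("id", "label", spiralpd:::feature_columns("F")))
  expect_error(subset_features(f, "P"), "does not contain")
})

test_that("train/test splits are stratified and reproducible", {
  tab <- blob_table(20)
  sp <- split_table(tab, 0.2, seed = 9)
  expect_equal(nrow(sp$test), 8)
  expect_equal(as.vector(table(sp$test$label)), c(4, 4))
  expect_equal(nrow(sp$train) + nrow(sp$test), 40)
  sp2 <- split_table(tab, 0.2, seed = 9)
  expect_identical(sp$test$id, sp2$test$id)
})
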