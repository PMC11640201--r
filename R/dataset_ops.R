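#' Rotate a grayscale image about its centre
#'
#' Bilinear resampling with white (255) fill for exposed corners; output has
#' the same dimensions as the input. Positive angles rotate the content
#' counterclockwise on screen. A 0-degree rotation returns the input
#' unchanged (bit-identical).
#'
#' @param image Grayscale matrix, intensities in \[0, 255\].
#' @param angle_deg Rotation angle in degrees.
#' @return Rotated matrix of the same shape.
#' @export
rotate_image <- function(image, angle_deg) {
  assert_gray_image(image)
  if (angle_deg %% 360 == 0) return(image)
  nr <- nrow(image)
  nc <- ncol(image)
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  # inverse mapping: for output (x, y), sample input at the point rotated by
  # -angle; y axis points down, so this rotates content CCW on screen
  xo <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  yo <- matrix(rep(seq_len(nr), nc), nr, nc) - cy
  xi <- cos(th) * xo - sin(th) * yo + cx
  yi <- sin(th) * xo + cos(th) * yo + cy

  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  get_px <- function(yy, xx) {
    ok <- xx >= 1 & xx <= nc & yy >= 1 & yy <= nr
    v <- matrix(255, nr, nc)
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- get_px(y0, x0)
  v01 <- get_px(y0, x0 + 1)
  v10 <- get_px(y0 + 1, x0)
  v11 <- get_px(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  pmin(pmax(out, 0), 255)
}

#' Rotation augmentation of a drawing
#'
#' Returns the image rotated at every angle from -45 to 165 degrees in
#' 15-degree steps (15 images); the 0-degree element is the unaltered input.
#' Rotation is the only label-preserving augmentation used: scaling would
#' destroy size cues (micrographia), shifting is irrelevant to centred
#' feature extraction, and blurring/brightening would corrupt the pencil
#' features.
#'
#' @param image Grayscale matrix, intensities in \[0, 255\].
#' @param angles Rotation angles in degrees (default `seq(-45, 165, by = 15)`).
#' @return Named list of rotated images (names are the angles).
#' @export
augment_rotations <- function(image, angles = seq(-45, 165, by = 15)) {
  assert_gray_image(image)
  out <- lapply(angles, function(a) rotate_image(image, a))
  names(out) <- as.character(angles)
  out
}

feature_columns <- function(feature_set = c("F", "P", "FP")) {
  feature_set <- match.arg(feature_set)
  fcols <- c("peak_magnitude", "peak_frequency", "snr", "variance", "bandwidth")
  pcols <- c("thickness", "pressure")
  switch(feature_set, F = fcols, P = pcols, FP = c(fcols, pcols))
}

#' Assemble the feature table for a set of drawings
#'
#' Runs the frequency and/or pencil feature pipelines over each image and
#' collects one row per drawing. Feature sets follow the F / P / FP naming:
#' frequency features only, pencil features only, or both. Pipeline failures
#' (self-intersecting or blank drawings) produce `NaN` values, not errors,
#' and are removed later by [clean_table()].
#'
#' @param images List of grayscale matrices, or a `labeled_spiral_set`.
#' @param labels Factor or character vector of `healthy`/`parkinson` labels
#'   (ignored when `images` is a `labeled_spiral_set`).
#' @param feature_set `"F"`, `"P"` or `"FP"`.
#' @param ids Optional row identifiers (default `img_001`, ...).
#' @param N Smoothing scale factor for the line of best fit.
#' @param draw_duration Nominal drawing time (s).
#' @return A data frame of class `feature_table` with columns `id`, `label`
#'   and the feature columns of the set; the set is kept in attribute
#'   `feature_set`.
#' @export
build_feature_table <- function(images, labels = NULL,
                                feature_set = c("FP", "F", "P"),
                                ids = NULL, N = 10, draw_duration = 10) {
  feature_set <- match.arg(feature_set)
  if (inherits(images, "labeled_spiral_set")) {
    labels <- images$labels
    if (is.null(ids) && nrow(images$manifest) > 0) ids <- images$manifest$id
    images <- images$images
  }
  if (length(images) == 0) stop("no images supplied", call. = FALSE)
  if (is.null(labels) || length(labels) != length(images)) {
    stop("`labels` must match `images` in length", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)

  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    rec <- list(id = as.character(ids[i]), label = as.character(labels[i]))
    if (feature_set %in% c("F", "FP")) {
      rec <- c(rec, frequency_features_image(img, N = N, draw_duration = draw_duration))
    }
    if (feature_set %in% c("P", "FP")) {
      pf <- tryCatch(extract_pencil_features(img),
                     error = function(e) list(thickness = NaN, pressure = NaN))
      rec <- c(rec, pf[c("thickness", "pressure")])
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "feature_set") <- feature_set
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Restrict a combined feature table to a smaller feature set
#'
#' An FP table contains both feature families, so the F-only and P-only
#' tables are column subsets of it; this avoids re-running the image
#' pipelines when comparing feature sets.
#'
#' @param table A `feature_table`.
#' @param feature_set Target set (must be a subset of the table's own).
#' @return A `feature_table` with the target set's columns.
#' @export
subset_features <- function(table, feature_set = c("F", "P", "FP")) {
  feature_set <- match.arg(feature_set)
  cols <- feature_columns(feature_set)
  if (!all(cols %in% names(table))) {
    stop(sprintf("table does not contain the %s feature columns", feature_set),
         call. = FALSE)
  }
  out <- table[, c("id", "label", cols), drop = FALSE]
  attr(out, "feature_set") <- feature_set
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Drop rows with undefined feature values
#'
#' Removes rows holding `NaN`/`NA` in any key feature column, preserving
#' order. Infinite SNR sentinels are kept (they are informative, not
#' missing).
#'
#' @param table A `feature_table`.
#' @return The cleaned table; errors if no row survives.
#' @export
clean_table <- function(table) {
  fs <- feature_set_of(table)
  cols <- feature_columns(fs)
  keep <- !apply(is.na(table[, cols, drop = FALSE]), 1, any)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("clean_table: removed %d row(s) with NaN features", dropped))
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("empty table after cleaning", call. = FALSE)
  attr(out, "feature_set") <- fs
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_set_of <- function(table) {
  fs <- attr(table, "feature_set")
  if (is.null(fs)) {
    has_f <- all(c("snr", "bandwidth") %in% names(table))
    has_p <- all(c("thickness", "pressure") %in% names(table))
    fs <- if (has_f && has_p) "FP" else if (has_f) "F" else if (has_p) "P" else
      stop("not a feature table", call. = FALSE)
  }
  fs
}

#' Write / read a feature table as CSV
#'
#' Comma-separated, header row, `.` decimal separator, `NaN` spelled `NaN`;
#' features round-trip at full double precision.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `write_feature_csv` returns the path invisibly;
#'   `read_feature_csv` returns a `feature_table`.
#' @export
write_feature_csv <- function(table, path) {
  fs <- feature_set_of(table)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.15g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in setdiff(names(df), c("id", "label"))) df[[j]] <- as.numeric(df[[j]])
  attr(df, "feature_set") <- feature_set_of(df)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Stratified train/test split of a feature table
#'
#' @param table A `feature_table`.
#' @param test_fraction Fraction of each class held out for testing
#'   (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables.
#' @export
split_table <- function(table, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  fs <- feature_set_of(table)
  with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(table)), table$label), function(ix) {
      n_test <- max(1L, round(length(ix) * test_fraction))
      sample(ix, n_test)
    }))
    out <- list(train = table[-test_idx, , drop = FALSE],
                test = table[sort(test_idx), , drop = FALSE])
    for (nm in names(out)) {
      attr(out[[nm]], "feature_set") <- fs
      class(out[[nm]]) <- c("feature_table", "data.frame")
    }
    out
  })
}
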