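#' Read a drawing as a grayscale matrix
#'
#' Loads a PNG/JPEG raster and reduces colour images to grayscale with the
#' standard luma weights (0.299 R + 0.587 G + 0.114 B). Drawings are assumed
#' dark-on-light.
#'
#' @param path File path.
#' @return Numeric matrix with intensities in \[0, 255\]; rows are y
#'   (top-down), columns are x.
#' @export
read_spiral_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path), call. = FALSE)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    nch <- dim(dat)[3]
    w <- if (nch >= 3) c(0.299, 0.587, 0.114) else rep(1 / nch, nch)
    gray <- matrix(0, dim(dat)[1], dim(dat)[2])
    for (k in seq_len(min(nch, 3))) gray <- gray + w[k] * dat[, , k]
  } else {
    gray <- dat
  }
  # EBImage stores x (column) in the first dimension; transpose to row = y.
  t(gray) * 255
}

#' Write a grayscale matrix to a PNG file
#'
#' @param image Numeric matrix with intensities in \[0, 255\].
#' @param path Output path (extension selects the format, typically `.png`).
#' @export
write_spiral_image <- function(image, path) {
  assert_gray_image(image)
  EBImage::writeImage(EBImage::Image(t(image) / 255), path)
  invisible(path)
}

# Gaussian kernel vector for a given odd size; sigma follows the usual
# size-derived rule sigma = 0.3 * ((size - 1)/2 - 1) + 0.8.
gaussian_kernel1d <- function(size) {
  stopifnot(size %% 2 == 1, size >= 1)
  sigma <- 0.3 * ((size - 1) * 0.5 - 1) + 0.8
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate padding.
convolve_sep <- function(m, k) {
  half <- (length(k) - 1) / 2
  pad_idx <- function(n) pmin(pmax(seq(1 - half, n + half), 1), n)
  # rows
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[seq(j, j + nrow(m) - 1), , drop = FALSE]
  }
  # cols
  mp <- out[, pad_idx(ncol(m)), drop = FALSE]
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    out2 <- out2 + k[j] * mp[, seq(j, j + ncol(m) - 1), drop = FALSE]
  }
  out2
}

#' Binarize a spiral drawing with Gaussian adaptive thresholding
#'
#' Applies a Gaussian noise filter, then marks as foreground every pixel that
#' is darker than its Gaussian-weighted local mean minus `offset_c`. This
#' separates dark strokes from the light paper background under uneven
#' illumination. Inverted-polarity images (light strokes on dark paper) are
#' unsupported and yield an empty mask / error.
#'
#' @param image Grayscale matrix, intensities in \[0, 255\].
#' @param blur_kernel Odd size of the Gaussian pre-filter (default 5).
#' @param block_size Odd neighbourhood size of the adaptive threshold
#'   (default 11).
#' @param offset_c Constant subtracted from the local mean (default 2).
#' @return Integer 0/1 matrix of the same shape (1 = stroke).
#' @export
binarize_spiral <- function(image, blur_kernel = 5, block_size = 11, offset_c = 2) {
  assert_gray_image(image)
  stopifnot(block_size %% 2 == 1, block_size >= 3)
  blurred <- if (blur_kernel > 1) {
    convolve_sep(image, gaussian_kernel1d(blur_kernel))
  } else {
    image
  }
  local_mean <- convolve_sep(blurred, gaussian_kernel1d(block_size))
  mask <- (blurred < local_mean - offset_c) * 1L
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0) stop("no foreground detected", call. = FALSE)
  mask
}

#' One-pixel skeleton by Zhang-Suen morphological thinning
#'
#' Iteratively peels boundary pixels of a binary mask with the two-subcycle
#' Zhang-Suen scheme until no pixel changes, leaving a one-pixel-wide,
#' topology-preserving skeleton. Thinning never adds pixels and is idempotent
#' on its own output.
#'
#' @param mask Binary (0/1) matrix with at least one foreground pixel.
#' @return Integer 0/1 matrix of the same shape (the skeleton).
#' @export
thin <- function(mask) {
  stopifnot(is.matrix(mask))
  if (sum(mask != 0) == 0) stop("mask has no foreground pixels", call. = FALSE)
  nr <- nrow(mask)
  nc <- ncol(mask)
  # pad with a 1-px zero border so neighbour lookups need no bounds checks
  pm <- matrix(0L, nr + 2L, nc + 2L)
  pm[2:(nr + 1), 2:(nc + 1)] <- (mask != 0) * 1L
  np <- nr + 2L
  # P2..P9 clockwise from north in (row = y down, col = x right) coordinates
  off <- c(-1L, -1L + np, np, 1L + np, 1L, 1L - np, -np, -1L - np)

  idx <- which(pm == 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      if (length(idx) == 0) break
      nbv <- matrix(0L, length(idx), 8L)
      for (k in 1:8) nbv[, k] <- pm[idx + off[k]]
      b <- rowSums(nbv)
      a <- integer(length(idx))
      for (k in 1:8) {
        k2 <- if (k == 8L) 1L else k + 1L
        a <- a + (nbv[, k] == 0L & nbv[, k2] == 1L)
      }
      if (sub == 1) {
        c1 <- nbv[, 1] * nbv[, 3] * nbv[, 5] == 0L
        c2 <- nbv[, 3] * nbv[, 5] * nbv[, 7] == 0L
      } else {
        c1 <- nbv[, 1] * nbv[, 3] * nbv[, 7] == 0L
        c2 <- nbv[, 1] * nbv[, 5] * nbv[, 7] == 0L
      }
      del <- b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        pm[idx[del]] <- 0L
        idx <- idx[!del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- pm[2:(nr + 1), 2:(nc + 1)]
  storage.mode(m) <- "integer"
  m
}

# Outer boundary chains of each connected component, largest-area first.
# Returns a list of data.frames with 1-based (x, y) pixel coordinates.
trace_contours <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(list())
  oc <- EBImage::ocontour(lab)
  out <- lapply(oc, function(m) {
    # ocontour returns 0-based coordinates in matrix (row, col) order when
    # fed a plain row-major matrix; map to x = col, y = row, 1-based.
    data.frame(x = m[, 2] + 1, y = m[, 1] + 1)
  })
  areas <- vapply(out, function(df) abs(polygon_area(cbind(df$x, df$y))), numeric(1))
  out[order(areas, decreasing = TRUE)]
}

#' Extract the largest contour of a binary mask
#'
#' Returns the outer boundary, among all connected components, that encloses
#' the maximal area — for a spiral drawing, the spiral path itself.
#'
#' @param mask Binary (0/1) matrix with foreground.
#' @return A data frame with ordered 8-connected boundary points in columns
#'   `x` (column px) and `y` (row px), 1-based, origin top-left.
#' @export
largest_contour <- function(mask) {
  stopifnot(is.matrix(mask))
  if (sum(mask != 0) == 0) stop("mask has no foreground pixels", call. = FALSE)
  ct <- trace_contours((mask != 0) * 1L)
  if (length(ct) == 0 || nrow(ct[[1]]) < 3) {
    stop("no contour found", call. = FALSE)
  }
  ct[[1]]
}
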