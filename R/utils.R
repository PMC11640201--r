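# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shift a matrix by (dy, dx) filling exposed entries with `fill`.
# dy > 0 moves content down, dx > 0 moves content right, so the result at
# (i, j) holds the input value at (i - dy, j - dx).
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

is_gray_image <- function(x) {
  is.matrix(x) && is.numeric(x) && length(x) > 0
}

assert_gray_image <- function(x, arg = "image") {
  if (!is_gray_image(x)) {
    stop(sprintf("`%s` must be a non-empty numeric matrix", arg), call. = FALSE)
  }
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 255) {
    stop(sprintf("`%s` must have intensities in [0, 255]", arg), call. = FALSE)
  }
  invisible(TRUE)
}

# Signed polygon area (shoelace); `xy` is a two-column matrix of vertices.
polygon_area <- function(xy) {
  x <- xy[, 1]
  y <- xy[, 2]
  n <- nrow(xy)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Area centroid of a polygon; falls back to the vertex mean for degenerate
# (zero-area) polygons handled by callers.
polygon_centroid <- function(xy) {
  a <- polygon_area(xy)
  if (abs(a) < .Machine$double.eps) {
    return(c(NA_real_, NA_real_))
  }
  x <- xy[, 1]
  y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  cx <- sum((x + x[j]) * cross) / (6 * a)
  cy <- sum((y + y[j]) * cross) / (6 * a)
  c(cx, cy)
}

# Perimeter of a closed pixel-chain polygon.
polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  j <- c(2:n, 1)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}
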