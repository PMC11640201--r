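#' Locate the spiral centre from its largest contour
#'
#' The centre is the area centroid of the contour polygon, rounded to the
#' nearest pixel. It anchors the polar unwrapping of the drawing.
#'
#' @param contour Data frame with ordered boundary points `x`, `y` (as
#'   returned by [largest_contour()]).
#' @return Named numeric vector `c(x, y)` in pixel coordinates.
#' @export
find_center <- function(contour) {
  stopifnot(is.data.frame(contour), all(c("x", "y") %in% names(contour)))
  if (nrow(contour) < 3) stop("degenerate contour", call. = FALSE)
  cen <- polygon_centroid(cbind(contour$x, contour$y))
  if (any(is.na(cen))) stop("degenerate (zero-area) contour", call. = FALSE)
  c(x = round(cen[1]), y = round(cen[2]))
}

#' Refine a spiral centre estimate from an unwrapped trace
#'
#' The area centroid of a spiral's contour is systematically offset from the
#' true spiral centre (the outermost, incomplete turn pulls it sideways by a
#' distance of the order of the radial growth rate). A centre offset
#' \eqn{(\Delta x, \Delta y)} shows up in the unwrapped trace as a
#' once-per-revolution wobble: \eqn{d_i \approx a\theta_i + \Delta x \cos
#' \phi_i + \Delta y \sin \phi_i}, with \eqn{\phi_i} the raw polar angle.
#' Regressing the distances on the angle and the direction cosines therefore
#' recovers the offset directly; adding it to the current centre cancels the
#' wobble. One or two iterations suffice.
#'
#' @param trace A `polar_trace` from [unwrap_spiral()].
#' @param center The centre `c(x, y)` the trace was unwrapped about.
#' @return Refined centre `c(x, y)` (not rounded).
#' @export
refine_center <- function(trace, center) {
  stopifnot(inherits(trace, "polar_trace"))
  d <- trace$distances
  ok <- d > .Machine$double.eps
  u <- (trace$x[ok] - center[["x"]]) / d[ok]
  v <- (trace$y[ok] - center[["y"]]) / d[ok]
  fit <- stats::lm.fit(cbind(1, trace$angles[ok], u, v), d[ok])
  c(x = center[["x"]] + unname(fit$coefficients[3]),
    y = center[["y"]] + unname(fit$coefficients[4]))
}

#' Unwrap a spiral skeleton into an angle--distance trace
#'
#' Walks the one-pixel skeleton path from its inner end outward, recording at
#' each pixel the Euclidean distance to the centre,
#' \eqn{d_i = \sqrt{(x_i - x_c)^2 + (y_i - y_c)^2}}, and the polar angle.
#' Per-pixel `atan2` angles are cumulatively phase-unwrapped (multiples of
#' \eqn{2\pi} are added so successive increments stay in \eqn{(-\pi, \pi)}),
#' making the angle continuous across revolutions; the sign is normalized so
#' angles increase along the trace, starting from the first pixel's principal
#' angle in \eqn{[0, 2\pi)}.
#'
#' The walk starts at the skeleton pixel nearest the centre and follows
#' unvisited 8-neighbours; a two-way ambiguity at a staircase corner takes
#' the 4-adjacent pixel first, and any other ambiguity is resolved by minimal
#' change of direction. If the start pixel lies mid-path the remaining branch
#' is walked too and prepended in reverse, so every pixel reachable from the
#' start appears exactly once. Junction pixels — crossing number (Rutovitz
#' 0-to-1 transitions around the 8-neighbourhood) of three or more, as at
#' self-intersections — make the drawing unusable and raise an error.
#'
#' @param skeleton Binary (0/1) matrix from [thin()].
#' @param center Named vector `c(x, y)` from [find_center()].
#' @return An object of class `polar_trace`: list with `angles` (radians,
#'   continuous and increasing), `distances` (px) and `n_points`.
#' @export
unwrap_spiral <- function(skeleton, center) {
  stopifnot(is.matrix(skeleton))
  sk <- (skeleton != 0)
  if (!any(sk)) stop("skeleton has no foreground pixels", call. = FALSE)
  nr <- nrow(sk)
  nc <- ncol(sk)
  xc <- as.numeric(center[["x"]])
  yc <- as.numeric(center[["y"]])
  if (xc < 1 || xc > nc || yc < 1 || yc > nr) {
    stop("center lies outside the image", call. = FALSE)
  }

  idx <- which(sk)
  ys <- ((idx - 1L) %% nr) + 1L
  xs <- ((idx - 1L) %/% nr) + 1L
  n_fg <- length(idx)

  # start at the skeleton pixel nearest the centroid, but skip stray speck
  # components (binarization noise) that would otherwise capture the walk:
  # a start pixel must belong to a component holding at least half of the
  # skeleton (8-connected breadth-first flood fill)
  component_of <- function(from) {
    seen <- matrix(FALSE, nr, nc)
    queue <- integer(n_fg)
    queue[1] <- from
    seen[from] <- TRUE
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      y <- ((cur - 1L) %% nr) + 1L
      x <- ((cur - 1L) %/% nr) + 1L
      cand <- cur + c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
      keep <- rep(TRUE, 8L)
      if (y == 1L) keep[c(1L, 5L, 7L)] <- FALSE
      if (y == nr) keep[c(2L, 6L, 8L)] <- FALSE
      if (x == 1L) keep[c(3L, 5L, 6L)] <- FALSE
      if (x == nc) keep[c(4L, 7L, 8L)] <- FALSE
      cand <- cand[keep]
      cand <- cand[sk[cand] & !seen[cand]]
      if (length(cand) > 0) {
        seen[cand] <- TRUE
        queue[(tail + 1L):(tail + length(cand))] <- cand
        tail <- tail + length(cand)
      }
    }
    queue[seq_len(tail)]
  }

  d2 <- (xs - xc)^2 + (ys - yc)^2
  ord <- order(d2)
  excluded <- matrix(FALSE, nr, nc)
  start <- NA_integer_
  for (cand_start in idx[ord]) {
    if (excluded[cand_start]) next
    comp <- component_of(cand_start)
    if (length(comp) >= n_fg / 2) {
      start <- cand_start
      # restrict the skeleton to this component
      sk <- matrix(FALSE, nr, nc)
      sk[comp] <- TRUE
      break
    }
    excluded[comp] <- TRUE
  }
  if (is.na(start)) {
    stop("unusable spiral: no dominant skeleton component", call. = FALSE)
  }

  # junction map: crossing number >= 3 marks a branch point
  m01 <- sk * 1L
  p <- list(
    shift_matrix(m01, +1, 0), shift_matrix(m01, +1, -1),
    shift_matrix(m01, 0, -1), shift_matrix(m01, -1, -1),
    shift_matrix(m01, -1, 0), shift_matrix(m01, -1, +1),
    shift_matrix(m01, 0, +1), shift_matrix(m01, +1, +1)
  )
  crossing <- matrix(0L, nr, nc)
  for (k in 1:8) {
    crossing <- crossing + (p[[k]] == 0L & p[[if (k == 8) 1 else k + 1]] == 1L)
  }
  junction <- sk & crossing >= 3L

  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  neigh <- function(i) {
    y <- ((i - 1L) %% nr) + 1L
    x <- ((i - 1L) %/% nr) + 1L
    cand <- i + off
    keep <- rep(TRUE, 8L)
    if (y == 1L) keep[c(1L, 5L, 7L)] <- FALSE
    if (y == nr) keep[c(2L, 6L, 8L)] <- FALSE
    if (x == 1L) keep[c(3L, 5L, 6L)] <- FALSE
    if (x == nc) keep[c(4L, 7L, 8L)] <- FALSE
    cand <- cand[keep]
    cand[sk[cand]]
  }

  visited <- matrix(FALSE, nr, nc)

  walk <- function(from, init_dir = NULL) {
    path <- integer(0)
    cur <- from
    prev_dir <- init_dir
    repeat {
      visited[cur] <<- TRUE
      path <- c(path, cur)
      if (junction[cur]) {
        stop("unusable spiral: skeleton junction encountered", call. = FALSE)
      }
      nb <- neigh(cur)
      nb <- nb[!visited[nb]]
      if (length(nb) == 0L) break
      if (length(nb) == 1L) {
        nxt <- nb
      } else {
        nbx <- ((nb - 1L) %/% nr) + 1L
        nby <- ((nb - 1L) %% nr) + 1L
        curx <- ((cur - 1L) %/% nr) + 1L
        cury <- ((cur - 1L) %% nr) + 1L
        four_adj <- abs(nbx - curx) + abs(nby - cury) == 1L
        mutually_adjacent <- length(nb) == 2L &&
          max(abs(nbx[1] - nbx[2]), abs(nby[1] - nby[2])) <= 1L
        if (mutually_adjacent && sum(four_adj) == 1L) {
          # staircase corner: take the 4-adjacent pixel first so the
          # diagonal one stays reachable
          nxt <- nb[four_adj]
        } else if (!is.null(prev_dir)) {
          dirs <- atan2(nby - cury, nbx - curx)
          dd <- abs(atan2(sin(dirs - prev_dir), cos(dirs - prev_dir)))
          nxt <- nb[which.min(dd)]
        } else {
          # at the very start with no direction: head inward first so the
          # second walk covers the outward branch
          dn <- (nbx - xc)^2 + (nby - yc)^2
          nxt <- nb[which.min(dn)]
        }
      }
      prev_dir <- atan2(((nxt - 1L) %% nr) + 1L - (((cur - 1L) %% nr) + 1L),
                        ((nxt - 1L) %/% nr) + 1L - (((cur - 1L) %/% nr) + 1L))
      cur <- nxt
    }
    path
  }

  # junction pre-check on the start pixel's component is implicit: walks
  # abort on any pixel with >= 3 unvisited-or-visited neighbours
  first <- walk(start)
  rest <- neigh(start)
  rest <- rest[!visited[rest]]
  path <- if (length(rest) >= 1L) {
    # continue the remaining branch outward, seeding its direction away
    # from the start pixel so the walk does not double back into stray
    # staircase pixels left beside the path
    sy <- ((start - 1L) %% nr) + 1L
    sx <- ((start - 1L) %/% nr) + 1L
    ry <- ((rest[1L] - 1L) %% nr) + 1L
    rx <- ((rest[1L] - 1L) %/% nr) + 1L
    second <- walk(rest[1L], init_dir = atan2(ry - sy, rx - sx))
    c(rev(first), second)
  } else {
    first
  }

  py <- ((path - 1L) %% nr) + 1L
  px <- ((path - 1L) %/% nr) + 1L
  dist <- sqrt((px - xc)^2 + (py - yc)^2)

  # order from the inner end outward
  if (dist[1] > dist[length(dist)]) {
    path <- rev(path)
    px <- rev(px)
    py <- rev(py)
    dist <- rev(dist)
  }

  if (length(path) < 2L) stop("unusable spiral: trace too short", call. = FALSE)

  raw <- atan2(py - yc, px - xc)
  dtheta <- diff(raw)
  dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))
  ang <- cumsum(c(raw[1], dtheta))
  # normalize so unwrapped angle increases along the trace
  if (ang[length(ang)] < ang[1]) ang <- -ang
  ang <- ang - ang[1] + (atan2(py[1] - yc, px[1] - xc) %% (2 * pi))

  structure(
    list(angles = ang, distances = dist, n_points = length(path),
         x = px, y = py),
    class = "polar_trace"
  )
}

#' @export
print.polar_trace <- function(x, ...) {
  cat(sprintf(
    "Polar trace: %d points, angle span %.2f rad (%.2f revolutions), radius %.1f-%.1f px\n",
    x$n_points, diff(range(x$angles)), diff(range(x$angles)) / (2 * pi),
    min(x$distances), max(x$distances)))
  invisible(x)
}

#' Write a polar trace as a two-column CSV
#'
#' @param trace A `polar_trace`.
#' @param path Output CSV path (columns `angle_rad`, `distance_px`).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "polar_trace"))
  utils::write.csv(
    data.frame(angle_rad = trace$angles, distance_px = trace$distances),
    path, row.names = FALSE)
  invisible(path)
}
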