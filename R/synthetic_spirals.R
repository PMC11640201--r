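#' Specify a synthetic Archimedean spiral drawing
#'
#' Defines the generative parameters of one simulated pencil drawing of a
#' guided Archimedean spiral \eqn{r = a\theta}. Tremor is modelled as an
#' additive radial sinusoid \eqn{r(\theta) = a\theta + A\sin(2\pi f t(\theta)
#' + \phi)} where the drawing time \eqn{t} advances uniformly along the arc
#' length of the path from 0 to `draw_duration`, so a spiral carries exactly
#' `tremor_frequency * draw_duration` tremor cycles regardless of its size.
#'
#' The default geometry emulates a guided spiral of 4.5 revolutions with a
#' 75 mm maximum radius rendered at 4 px/mm (hence `a = 300 / (9 * pi)`),
#' drawn clockwise. The innermost `start_angle` radians of the guide are
#' skipped so the stroke never self-overlaps at the centre, where the curve's
#' radius of curvature would fall below the stroke half-width.
#'
#' @param a Radial growth rate in pixels per radian (must be positive).
#' @param revolutions Number of revolutions (default 4.5).
#' @param tremor_amplitude Radial tremor amplitude A in pixels (>= 0).
#' @param tremor_frequency Tremor frequency f in Hz (>= 0).
#' @param draw_duration Nominal drawing time in seconds (default 10).
#' @param stroke_width Pencil stroke width in pixels.
#' @param stroke_intensity Mean grayscale intensity of stroke pixels (dark,
#'   0--255).
#' @param intensity_jitter Standard deviation of per-pixel intensity noise.
#' @param image_size Side of the square canvas in pixels; by default sized to
#'   fit the spiral with a small margin.
#' @param direction `"clockwise"` (default, as in guided drawings) or
#'   `"counterclockwise"`.
#' @param start_angle Angle (radians) at which the drawn stroke starts.
#' @param tremor_phase Tremor phase in radians, or `NULL` to draw it from the
#'   seeded RNG.
#' @param seed Integer seed making the rendering reproducible.
#'
#' @return An object of class `spiral_spec`.
#' @seealso [render_spiral()], [make_labeled_set()]
#' @export
spiral_spec <- function(a = 75 * 4 / (2 * pi * 4.5),
                        revolutions = 4.5,
                        tremor_amplitude = 0,
                        tremor_frequency = 0,
                        draw_duration = 10,
                        stroke_width = 3,
                        stroke_intensity = 80,
                        intensity_jitter = 5,
                        image_size = NULL,
                        direction = c("clockwise", "counterclockwise"),
                        start_angle = 0.5,
                        tremor_phase = NULL,
                        seed = 1L) {
  direction <- match.arg(direction)
  max_radius <- a * 2 * pi * revolutions
  if (is.null(image_size)) {
    image_size <- 2L * as.integer(ceiling(
      max_radius + tremor_amplitude + stroke_width + 12
    ))
  }
  spec <- structure(
    list(
      a = a, revolutions = revolutions,
      tremor_amplitude = tremor_amplitude,
      tremor_frequency = tremor_frequency,
      draw_duration = draw_duration,
      stroke_width = stroke_width,
      stroke_intensity = stroke_intensity,
      intensity_jitter = intensity_jitter,
      image_size = as.integer(image_size),
      direction = direction,
      start_angle = start_angle,
      tremor_phase = tremor_phase,
      seed = as.integer(seed)
    ),
    class = "spiral_spec"
  )
  validate_spiral_spec(spec)
  spec
}

validate_spiral_spec <- function(spec) {
  with(spec, {
    if (!(a > 0)) stop("`a` must be positive", call. = FALSE)
    if (!(revolutions > 0)) stop("`revolutions` must be positive", call. = FALSE)
    if (tremor_amplitude < 0) stop("`tremor_amplitude` must be >= 0", call. = FALSE)
    if (tremor_frequency < 0) stop("`tremor_frequency` must be >= 0", call. = FALSE)
    if (draw_duration <= 0) stop("`draw_duration` must be positive", call. = FALSE)
    if (stroke_width <= 0) stop("`stroke_width` must be positive", call. = FALSE)
    if (intensity_jitter < 0) stop("`intensity_jitter` must be >= 0", call. = FALSE)
    if (stroke_intensity + 3 * intensity_jitter >= 255) {
      stop("stroke_intensity + 3 * intensity_jitter must stay below the white background (255)",
           call. = FALSE)
    }
    if (start_angle < 0 || start_angle >= 2 * pi * revolutions) {
      stop("`start_angle` must lie in [0, 2 * pi * revolutions)", call. = FALSE)
    }
    if (a * 2 * pi * revolutions + tremor_amplitude + stroke_width >= image_size / 2) {
      stop("spiral exceeds canvas", call. = FALSE)
    }
  })
  invisible(spec)
}

#' @export
print.spiral_spec <- function(x, ...) {
  cat("Synthetic Archimedean spiral spec\n")
  cat(sprintf("  r = a*theta with a = %.3f px/rad, %.1f revolutions (%s)\n",
              x$a, x$revolutions, x$direction))
  cat(sprintf("  tremor: A = %.2f px at f = %.2f Hz over %.1f s\n",
              x$tremor_amplitude, x$tremor_frequency, x$draw_duration))
  cat(sprintf("  stroke: width %.1f px, intensity %.0f +/- %.1f on white 255\n",
              x$stroke_width, x$stroke_intensity, x$intensity_jitter))
  cat(sprintf("  canvas: %d x %d px, seed %d\n", x$image_size, x$image_size, x$seed))
  invisible(x)
}

# Arc length of r = a*theta from 0 to theta (closed form).
spiral_arclen <- function(a, theta) {
  (a / 2) * (theta * sqrt(theta^2 + 1) + asinh(theta))
}

#' Render a synthetic spiral drawing to a grayscale raster
#'
#' Rasterizes the polar curve of a [spiral_spec()] as a stroke of finite
#' width on a white (255) background. The curve is sampled at sub-pixel arc
#' steps and stamped with a disk of diameter `stroke_width`; no anti-aliasing
#' is applied, so stroke pixels carry `stroke_intensity` plus optional
#' Gaussian jitter and background pixels are exactly 255. Rendering is
#' bit-reproducible for identical spec and seed.
#'
#' @param spec A [spiral_spec()].
#' @return A numeric `image_size x image_size` matrix (rows are y, columns
#'   are x, origin top-left) with values in \[0, 255\]. Attributes record the
#'   generative ground truth: `spec`, `center` (x, y of the spiral centre),
#'   `stroke_idx` (linear indices of stroke pixels) and `path_length`
#'   (arc length of the drawn curve in px).
#' @export
render_spiral <- function(spec) {
  stopifnot(inherits(spec, "spiral_spec"))
  validate_spiral_spec(spec)
  with_seed(spec$seed, {
    phase <- if (is.null(spec$tremor_phase)) runif(1, 0, 2 * pi) else spec$tremor_phase

    theta_max <- 2 * pi * spec$revolutions
    theta0 <- spec$start_angle
    # Uniform arc-length sampling finer than one pixel so stamped disks
    # overlap into a continuous stroke.
    s0 <- spiral_arclen(spec$a, theta0)
    s1 <- spiral_arclen(spec$a, theta_max)
    step <- 0.35
    s_grid <- seq(s0, s1, by = step)
    # Invert s(theta) on a dense monotone grid.
    th_dense <- seq(theta0, theta_max, length.out = 16384)
    s_dense <- spiral_arclen(spec$a, th_dense)
    theta <- stats::approx(s_dense, th_dense, xout = s_grid, rule = 2)$y

    t_along <- (s_grid - s0) / (s1 - s0) * spec$draw_duration
    r <- spec$a * theta +
      spec$tremor_amplitude * sin(2 * pi * spec$tremor_frequency * t_along + phase)
    r[r < 0] <- 0

    ang <- if (spec$direction == "clockwise") theta else -theta
    cx <- ceiling(spec$image_size / 2)
    cy <- ceiling(spec$image_size / 2)
    # Image coordinates: x = column, y = row, y axis pointing down, so
    # increasing theta traces a clockwise curve on screen.
    px <- cx + r * cos(ang)
    py <- cy + r * sin(ang)

    n <- spec$image_size
    half <- spec$stroke_width / 2
    rad <- floor(half + 0.499)
    offs <- expand.grid(dx = -rad:rad, dy = -rad:rad)
    offs <- offs[offs$dx^2 + offs$dy^2 <= half^2 + 1e-9, , drop = FALSE]

    xs0 <- round(px)
    ys0 <- round(py)
    idx <- integer(0)
    for (k in seq_len(nrow(offs))) {
      xs <- xs0 + offs$dx[k]
      ys <- ys0 + offs$dy[k]
      ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= n
      idx <- c(idx, (xs[ok] - 1L) * n + ys[ok])
    }
    idx <- unique(as.integer(idx))

    img <- matrix(255, n, n)
    vals <- spec$stroke_intensity + stats::rnorm(length(idx), 0, spec$intensity_jitter)
    img[idx] <- pmin(pmax(vals, 0), 255)

    attr(img, "spec") <- spec
    attr(img, "center") <- c(x = cx, y = cy)
    attr(img, "stroke_idx") <- idx
    attr(img, "path_length") <- s1 - s0
    attr(img, "tremor_phase") <- phase
    img
  })
}

#' Parameter ranges for simulated healthy and Parkinsonian cohorts
#'
#' Each range is a `c(min, max)` pair sampled uniformly per drawing. Healthy
#' drawings carry at most sub-pixel radial tremor and dark, firm strokes;
#' Parkinsonian drawings carry a 4--6 Hz radial tremor of several pixels
#' (the classical parkinsonian tremor band) and lighter strokes, reflecting
#' the reduced pen pressure reported for PD handwriting.
#'
#' @param group `"healthy"` or `"parkinson"`.
#' @param px_per_mm Rendering scale mapping the 75 mm guide radius to pixels
#'   (default 4).
#' @return A named list of `c(min, max)` ranges understood by
#'   [make_labeled_set()].
#' @export
spiral_ranges <- function(group = c("healthy", "parkinson"), px_per_mm = 4) {
  group <- match.arg(group)
  a_nom <- px_per_mm * 75 / (2 * pi * 4.5)
  common <- list(
    a = a_nom * c(0.9, 1.0),
    revolutions = c(4.5, 4.5),
    draw_duration = c(10, 10),
    intensity_jitter = c(5, 5)
  )
  if (group == "healthy") {
    c(common, list(
      tremor_amplitude = c(0, 0.8),
      tremor_frequency = c(0.5, 2),
      stroke_width = c(3, 4),
      stroke_intensity = c(60, 100)
    ))
  } else {
    c(common, list(
      tremor_amplitude = c(3, 8),
      tremor_frequency = c(4, 6),
      stroke_width = c(2, 3),
      stroke_intensity = c(120, 160)
    ))
  }
}

#' Generate a labeled set of synthetic spiral drawings
#'
#' Samples `n_healthy` specs from the healthy ranges and `n_pd` from the
#' Parkinsonian ranges, renders each, and records every sampled parameter in
#' a manifest so downstream stages can be checked against ground truth.
#'
#' @param n_healthy,n_pd Number of drawings per class (>= 0).
#' @param healthy_ranges,pd_ranges Named lists of `c(min, max)` ranges as
#'   produced by [spiral_ranges()].
#' @param seed Integer seed; identical arguments and seed reproduce the set
#'   exactly.
#' @return An object of class `labeled_spiral_set`: a list with `images`
#'   (list of matrices), `labels` (factor with levels healthy/parkinson) and
#'   `manifest` (data frame of sampled parameters, one row per image).
#' @export
make_labeled_set <- function(n_healthy, n_pd,
                             healthy_ranges = spiral_ranges("healthy"),
                             pd_ranges = spiral_ranges("parkinson"),
                             seed = 1L) {
  stopifnot(n_healthy >= 0, n_pd >= 0)
  check_ranges <- function(rg, who) {
    needed <- c("a", "tremor_amplitude", "tremor_frequency", "stroke_width",
                "stroke_intensity")
    if (!all(needed %in% names(rg)) ||
        !all(vapply(rg, function(v) is.numeric(v) && length(v) == 2 && v[2] >= v[1],
                    logical(1)))) {
      stop(sprintf("invalid or empty %s spec ranges", who), call. = FALSE)
    }
  }
  if (n_healthy > 0) check_ranges(healthy_ranges, "healthy")
  if (n_pd > 0) check_ranges(pd_ranges, "parkinson")

  labels <- factor(rep(c("healthy", "parkinson"), c(n_healthy, n_pd)),
                   levels = c("healthy", "parkinson"))
  n <- length(labels)
  with_seed(seed, {
    seeds <- if (n > 0) sample.int(2^31 - 2, n) else integer(0)
    draw <- function(rg, field) runif(1, rg[[field]][1], rg[[field]][2])
    images <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rg <- if (labels[i] == "healthy") healthy_ranges else pd_ranges
      spec <- spiral_spec(
        a = draw(rg, "a"),
        revolutions = if (!is.null(rg$revolutions)) draw(rg, "revolutions") else 4.5,
        tremor_amplitude = draw(rg, "tremor_amplitude"),
        tremor_frequency = draw(rg, "tremor_frequency"),
        draw_duration = if (!is.null(rg$draw_duration)) draw(rg, "draw_duration") else 10,
        stroke_width = draw(rg, "stroke_width"),
        stroke_intensity = draw(rg, "stroke_intensity"),
        intensity_jitter = if (!is.null(rg$intensity_jitter)) draw(rg, "intensity_jitter") else 5,
        seed = seeds[i]
      )
      images[[i]] <- render_spiral(spec)
      rows[[i]] <- data.frame(
        id = sprintf("%s_%03d", labels[i], i),
        label = as.character(labels[i]),
        a = spec$a,
        revolutions = spec$revolutions,
        tremor_amplitude = spec$tremor_amplitude,
        tremor_frequency = spec$tremor_frequency,
        stroke_width = spec$stroke_width,
        stroke_intensity = spec$stroke_intensity,
        intensity_jitter = spec$intensity_jitter,
        image_size = spec$image_size,
        seed = spec$seed,
        stringsAsFactors = FALSE
      )
    }
    structure(
      list(
        images = images,
        labels = labels,
        manifest = if (n > 0) do.call(rbind, rows) else
          data.frame(id = character(0), label = character(0))
      ),
      class = "labeled_spiral_set"
    )
  })
}

#' @export
print.labeled_spiral_set <- function(x, ...) {
  cat(sprintf("Labeled synthetic spiral set: %d images (%d healthy, %d parkinson)\n",
              length(x$images),
              sum(x$labels == "healthy"), sum(x$labels == "parkinson")))
  invisible(x)
}
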