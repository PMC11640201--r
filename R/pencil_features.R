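#' Refined intensity threshold isolating pencil strokes
#'
#' The initial threshold is the mean intensity of all pixels; the error
#' margin is its distance to white (255), and the refined threshold is the
#' mean minus that margin, i.e. `2 * mean - 255`, clamped to \[0, 255\].
#' On a mostly-white page this lands between the paper and the strokes.
#'
#' @param image Grayscale matrix, intensities in \[0, 255\].
#' @return Threshold intensity.
#' @export
pencil_threshold <- function(image) {
  assert_gray_image(image)
  m <- mean(image)
  min(max(2 * m - 255, 0), 255)
}

#' Pencil thickness and pressure features
#'
#' Stroke pixels are those strictly below the refined threshold. Pressure is
#' their mean grayscale intensity (darker strokes imply heavier pressure, so
#' lower values mean more pressure). Thickness is the stroke pixel count
#' divided by the total contour arc length of the stroke mask; since the
#' boundary of a ribbon-like stroke runs along both sides, this is a
#' consistent relative thickness measure, roughly half the geometric stroke
#' width, not the literal width in px. Both features are `NaN` when the mask
#' is empty or has no measurable contour.
#'
#' @param image Grayscale matrix, intensities in \[0, 255\].
#' @param include_holes Also count the boundaries of interior holes in the
#'   arc length (default `TRUE`).
#' @return Named list with `thickness` (px), `pressure` (grayscale 0--255)
#'   and `final_threshold`.
#' @export
extract_pencil_features <- function(image, include_holes = TRUE) {
  assert_gray_image(image)
  thr <- pencil_threshold(image)
  mask <- (image < thr) * 1L
  n_stroke <- sum(mask)
  if (n_stroke == 0) {
    return(list(thickness = NaN, pressure = NaN, final_threshold = thr))
  }
  pressure <- mean(image[mask == 1L])

  outer_len <- sum(vapply(trace_contours(mask),
                          function(df) polygon_perimeter(cbind(df$x, df$y)),
                          numeric(1)))
  hole_len <- 0
  if (include_holes) {
    # holes = background components not touching the border
    bg <- 1L - mask
    lab <- EBImage::bwlabel(bg)
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    hole_mask <- (lab > 0 & !(lab %in% border_labels)) * 1L
    if (sum(hole_mask) > 0) {
      hole_len <- sum(vapply(trace_contours(hole_mask),
                             function(df) polygon_perimeter(cbind(df$x, df$y)),
                             numeric(1)))
    }
  }
  total_len <- outer_len + hole_len
  if (total_len <= 0) {
    return(list(thickness = NaN, pressure = NaN, final_threshold = thr))
  }
  list(
    thickness = n_stroke / total_len,
    pressure = pressure,
    final_threshold = thr
  )
}
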