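#' Pixel calibration: physical size of one pixel
#'
#' Converts pixel counts into physical units: `pixel_area_cm2` is the exact
#' product of the per-axis factors, so orifice areas in cm^2 come from
#' multiplying the enclosed pixel count by the area assigned to each pixel.
#'
#' @param cm_per_px_x,cm_per_px_y centimetres spanned by one pixel along the
#'   image x (column) and y (row) axes; both must be positive
#' @return object of class `pixel_calibration`
#' @export
explicit_calibration <- function(cm_per_px_x, cm_per_px_y = cm_per_px_x) {
  if (!is.numeric(cm_per_px_x) || !is.numeric(cm_per_px_y) ||
      length(cm_per_px_x) != 1L || length(cm_per_px_y) != 1L ||
      is.na(cm_per_px_x) || is.na(cm_per_px_y) ||
      cm_per_px_x <= 0 || cm_per_px_y <= 0)
    stop_validation("calibration factors must be single positive numbers")
  structure(
    list(cm_per_px_x = as.numeric(cm_per_px_x),
         cm_per_px_y = as.numeric(cm_per_px_y),
         pixel_area_cm2 = as.numeric(cm_per_px_x) * as.numeric(cm_per_px_y)),
    class = "pixel_calibration"
  )
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration: %.5g x %.5g cm/px (%.5g cm2/px)>\n",
              x$cm_per_px_x, x$cm_per_px_y, x$pixel_area_cm2))
  invisible(x)
}

#' Calibrate from paired green ruler dots (Philips dialect)
#'
#' Philips exports carry a ruler of green dots at a known physical spacing;
#' the pixel size follows from the distance between the centroids of two
#' consecutive dots. A pixel counts as "green" when its G channel is at least
#' `green_min` and exceeds both R and B by `green_tolerance`; dots are
#' 8-connected components of green pixels and centroids are unweighted means
#' of member coordinates. With more than two dots the median consecutive gap
#' is used, which is robust to a single miss-detected blob.
#'
#' @param frame an RGB frame array `(h, w, 3)`
#' @param green_tolerance margin by which G must exceed R and B (default 60)
#' @param spacing_cm physical distance between consecutive dots; the vendor
#'   ruler spacing is configuration, not part of the video (default 1.0 cm)
#' @param green_min minimum absolute G intensity (default 100)
#' @return a `pixel_calibration` (isotropic unless a second ruler is found)
#' @export
calibrate_philips <- function(frame, green_tolerance = 60, spacing_cm = 1.0,
                              green_min = 100) {
  if (spacing_cm <= 0) stop_validation("spacing_cm must be positive")
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  green <- (g >= green_min) & ((g - r) >= green_tolerance) &
    ((g - b) >= green_tolerance)
  if (!any(green))
    stop_calibration("no green calibration markers found in frame")
  labels <- cpp_label_components(green, 8L)
  k <- max(labels)
  if (k < 2L)
    stop_calibration("fewer than two green marker dots detected")
  cent <- t(vapply(seq_len(k), function(i) {
    idx <- which(labels == i, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
  # order the dots along the ruler axis (the axis of larger centroid spread)
  axis <- if (diff(range(cent[, 1])) >= diff(range(cent[, 2]))) 1L else 2L
  cent <- cent[order(cent[, axis]), , drop = FALSE]
  gaps <- sqrt(rowSums(diff(cent)^2))
  gap_px <- stats::median(gaps)
  if (!is.finite(gap_px) || gap_px <= 0)
    stop_calibration("green marker centroids are not separated")
  explicit_calibration(spacing_cm / gap_px)
}

#' Calibrate from a scale line (GE dialect)
#'
#' GE exports draw a straight bright line of known physical length in the
#' lower-right corner. Pixel width is that length divided by the line's
#' extent in pixels; pixel height is assumed equal (symmetric-pixel
#' assumption).
#'
#' @param frame an RGB frame array `(h, w, 3)`
#' @param region integer vector `c(row_min, row_max, col_min, col_max)`
#'   bounding the search area; defaults to the lower-right quadrant
#' @param line_length_cm configured physical length of the line (default 1.0)
#' @param brightness minimum luminance for a pixel to belong to the line
#' @return a `pixel_calibration`
#' @export
calibrate_ge <- function(frame, region = NULL, line_length_cm = 1.0,
                         brightness = 200) {
  if (line_length_cm <= 0) stop_validation("line_length_cm must be positive")
  d <- dim(frame)
  if (is.null(region))
    region <- c(d[1] %/% 2L + 1L, d[1], d[2] %/% 2L + 1L, d[2])
  region <- as.integer(region)
  if (length(region) != 4L || region[1] > region[2] || region[3] > region[4] ||
      region[1] < 1L || region[2] > d[1] || region[3] < 1L || region[4] > d[2])
    stop_validation("region must be c(row_min, row_max, col_min, col_max) inside the frame")
  sub <- frame[region[1]:region[2], region[3]:region[4], , drop = FALSE]
  lum <- to_grayscale(sub)
  bright <- which(lum >= brightness, arr.ind = TRUE)
  if (nrow(bright) == 0L)
    stop_calibration("no scale line detected in the given region")
  row_span <- diff(range(bright[, 1])) + 1L
  col_span <- diff(range(bright[, 2])) + 1L
  len_px <- max(row_span, col_span)
  if (len_px < 2L)
    stop_calibration("detected scale mark is too short to measure")
  explicit_calibration(line_length_cm / len_px)
}
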