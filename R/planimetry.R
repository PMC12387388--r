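#' Convert an RGB frame to grayscale by luminance
#'
#' Uses the luminance weighting `0.2989 R + 0.5870 G + 0.1140 B`, which gives
#' the G channel the largest weight in line with the eye's sensitivity.
#' Results are rounded half-up to the nearest integer and clipped to
#' `[0, 255]`.
#'
#' @param frame integer array `(h, w, 3)` in RGB order
#' @return integer matrix `(h, w)` of gray intensities in `[0, 255]`
#' @export
to_grayscale <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stop_validation("to_grayscale() expects an (h, w, 3) RGB array")
  lum <- 0.2989 * frame[, , 1] + 0.5870 * frame[, , 2] + 0.1140 * frame[, , 3]
  g <- as.integer(pmin(255, pmax(0, floor(lum + 0.5))))
  matrix(g, nrow = d[1], ncol = d[2])
}

#' Single-band fixed thresholding
#'
#' Maps a gray image to binary: a pixel becomes 1 exactly when its intensity
#' strictly exceeds the threshold, 0 otherwise. In the 8-bit setting the
#' threshold must be strictly between 0 and 255. In the thresholded image,
#' 1-pixels are the bright tissue surfaces and 0-pixels the dark spaces
#' between them; an enclosed 0-region between tissue surfaces is the valve
#' orifice.
#'
#' @param gray integer matrix of intensities in `[0, 255]`
#' @param threshold integer gray level, `0 < threshold < 255`
#' @return integer matrix of 0/1 bits, same dimensions as `gray`
#' @export
binarize <- function(gray, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 255)
    stop_validation("threshold must lie strictly between 0 and 255")
  out <- matrix(0L, nrow = nrow(gray), ncol = ncol(gray))
  out[gray > threshold] <- 1L
  out
}

#' Locate the valve orifice in a binary mask
#'
#' The orifice is the largest connected dark (0-valued) region that is fully
#' enclosed by bright pixels — i.e. it does not touch the image border, which
#' distinguishes it from the dark background surrounding the tissue. Dark
#' regions are 4-connected (so the bright enclosure cannot be leaked through
#' diagonally); the returned boundary is the Moore (8-neighbour) trace of the
#' region's own outermost pixels.
#'
#' Area is the enclosed pixel count times the per-pixel area from the
#' calibration. Perimeter is the polygonal arc length of the closed boundary
#' path through pixel centres, with each step scaled per axis
#' (`cm_per_px_x`/`cm_per_px_y`; diagonal steps combine the two in the
#' Euclidean norm).
#'
#' @param mask integer 0/1 matrix from [binarize()]
#' @param calibration a `pixel_calibration`
#' @return an `orifice_contour` (fields `boundary`, `interior_pixel_count`,
#'   `area_cm2`, `perimeter_cm`), or `NULL` when no enclosed dark region
#'   exists (valve closed)
#' @export
find_orifice_contour <- function(mask, calibration) {
  if (!inherits(calibration, "pixel_calibration"))
    stop_validation("calibration must be a pixel_calibration")
  dark <- mask == 0L
  if (!any(dark)) return(NULL)
  labels <- cpp_label_components(dark, 4L)
  nr <- nrow(labels); nc <- ncol(labels)
  border <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
  border <- border[border != 0L]
  k <- max(labels)
  candidates <- setdiff(seq_len(k), border)
  if (length(candidates) == 0L) return(NULL)
  sizes <- tabulate(labels, nbins = k)
  lab <- candidates[which.max(sizes[candidates])]  # ties: lowest label id
  region <- labels == lab
  boundary <- cpp_trace_boundary(region)
  structure(
    list(boundary = boundary,
         interior_pixel_count = sizes[lab],
         area_cm2 = sizes[lab] * calibration$pixel_area_cm2,
         perimeter_cm = contour_perimeter_cm(boundary, calibration)),
    class = "orifice_contour"
  )
}

# closed-polygon arc length of a boundary path, cm per axis
contour_perimeter_cm <- function(boundary, calibration) {
  n <- nrow(boundary)
  if (n < 2L) return(0)
  nxt <- c(2:n, 1L)
  dy <- (boundary[nxt, 1] - boundary[, 1]) * calibration$cm_per_px_y
  dx <- (boundary[nxt, 2] - boundary[, 2]) * calibration$cm_per_px_x
  sum(sqrt(dx^2 + dy^2))
}

#' @export
print.orifice_contour <- function(x, ...) {
  cat(sprintf("<orifice_contour: %d px, area %.3f cm2, perimeter %.3f cm>\n",
              x$interior_pixel_count, x$area_cm2, x$perimeter_cm))
  invisible(x)
}

#' Frame of maximum valve opening at one threshold
#'
#' Applies grayscale conversion, thresholding and orifice detection to every
#' frame of the sequence and returns the record of the frame with the largest
#' orifice area. Frames with no enclosed orifice score area 0; ties on the
#' maximum area resolve to the earliest frame index.
#'
#' @param seq a `frame_sequence`
#' @param threshold integer gray threshold
#' @param calibration a `pixel_calibration`
#' @return one-row tibble with columns `threshold`, `best_frame_index`,
#'   `area_cm2`, `perimeter_cm`, and a list column `contour` holding the
#'   winning frame's `orifice_contour` (or `NULL`)
#' @export
max_opening_frame <- function(seq, threshold, calibration) {
  if (!inherits(seq, "frame_sequence") || length(seq) < 1L)
    stop_validation("seq must be a non-empty frame_sequence")
  best <- list(area = -1, perim = 0, idx = 1L, contour = NULL)
  for (i in seq_along(seq$frames)) {
    ct <- find_orifice_contour(
      binarize(to_grayscale(seq$frames[[i]]), threshold), calibration)
    area <- if (is.null(ct)) 0 else ct$area_cm2
    if (area > best$area) {
      best <- list(area = area,
                   perim = if (is.null(ct)) 0 else ct$perimeter_cm,
                   idx = i, contour = ct)
    }
  }
  tibble(threshold = as.integer(threshold),
         best_frame_index = best$idx,
         area_cm2 = best$area,
         perimeter_cm = best$perim,
         contour = list(best$contour))
}

#' Incremental threshold scan for the maximum valve opening
#'
#' Thresholds are applied sequentially from `t_min` upwards; at each one the
#' frame with the largest orifice area is selected. The scan stops at the
#' first threshold whose best-contour perimeter differs from the previous
#' threshold's by more than `perimeter_jump_cm` (the abrupt-change guard), in
#' which case the penultimate threshold analysed is selected; otherwise it
#' runs to `t_max` and selects it. The selected record's area is the measured
#' maximum mitral valve opening (MVA) in cm^2.
#'
#' @param seq a `frame_sequence`
#' @param calibration a `pixel_calibration`
#' @param t_min,t_max inclusive threshold range scanned (defaults 10 and 30)
#' @param perimeter_jump_cm stop criterion on the absolute perimeter
#'   difference between consecutive thresholds (default 1.0 cm)
#' @return an object of class `mva_scan`: fields `records` (tibble of all
#'   visited thresholds), `selected_threshold`, `selected_frame_index`,
#'   `mva_cm2`, `stop_reason` (`"perimeter_jump"` or `"threshold_cap"`)
#' @export
threshold_scan <- function(seq, calibration, t_min = 10L, t_max = 30L,
                           perimeter_jump_cm = 1.0) {
  if (!inherits(seq, "frame_sequence") || length(seq) < 1L)
    stop_validation("seq must be a non-empty frame_sequence")
  t_min <- as.integer(t_min); t_max <- as.integer(t_max)
  if (t_min > t_max) stop_validation("t_min must not exceed t_max")
  if (t_min <= 0L || t_max >= 255L)
    stop_validation("thresholds must lie strictly between 0 and 255")

  records <- vector("list", t_max - t_min + 1L)
  stop_reason <- "threshold_cap"
  last_perim <- NULL
  n_visited <- 0L
  for (t in t_min:t_max) {
    rec <- max_opening_frame(seq, t, calibration)
    n_visited <- n_visited + 1L
    records[[n_visited]] <- rec
    if (!is.null(last_perim) &&
        abs(rec$perimeter_cm - last_perim) > perimeter_jump_cm) {
      stop_reason <- "perimeter_jump"
      break
    }
    last_perim <- rec$perimeter_cm
  }
  records <- bind_rows(records[seq_len(n_visited)])
  sel <- if (stop_reason == "perimeter_jump") n_visited - 1L else n_visited
  selected <- records[sel, ]
  structure(
    list(records = records,
         selected_threshold = selected$threshold,
         selected_frame_index = selected$best_frame_index,
         mva_cm2 = selected$area_cm2,
         stop_reason = stop_reason,
         perimeter_jump_cm = perimeter_jump_cm,
         calibration = calibration),
    class = "mva_scan"
  )
}

#' @export
print.mva_scan <- function(x, ...) {
  cat(sprintf(
    "<mva_scan: %d threshold(s) visited, selected t=%d (frame %d), MVA %.3f cm2, stop: %s>\n",
    nrow(x$records), x$selected_threshold, x$selected_frame_index,
    x$mva_cm2, x$stop_reason))
  invisible(x)
}
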