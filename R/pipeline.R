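#' End-to-end planimetry diagnosis of one video
#'
#' Runs the full measurement chain: frame extraction, pixel calibration
#' (from vendor markers or supplied explicitly), the incremental threshold
#' scan, and severity grading of the resulting maximum valve opening area.
#'
#' @param video_path path to an AVI video
#' @param calib_mode `"philips"` (green ruler dots), `"ge"` (scale line) or
#'   `"explicit"` (pass `calibration`)
#' @param calibration a `pixel_calibration`, required when
#'   `calib_mode = "explicit"`
#' @param marker_spacing_cm physical dot spacing / line length used by the
#'   marker-based modes (default 1.0 cm)
#' @param t_min,t_max,perimeter_jump_cm threshold-scan settings (defaults
#'   10, 30, 1.0)
#' @param out_dir if given, a JSON report and a PNG overlay of the selected
#'   frame (contour drawn as a solid white line, area printed) are written
#'   here
#' @return object of class `dip_report`: `video`, `calibration`, `scan` (an
#'   `mva_scan`), `mva_cm2`, `grade`, `selected_frame_index`, plus the paths
#'   of any artifacts written
#' @export
run_dip <- function(video_path, calib_mode = c("explicit", "philips", "ge"),
                    calibration = NULL, marker_spacing_cm = 1.0,
                    t_min = 10L, t_max = 30L, perimeter_jump_cm = 1.0,
                    out_dir = NULL) {
  calib_mode <- match.arg(calib_mode)
  seq <- extract_frames(video_path, vendor_dialect = calib_mode)
  if (calib_mode == "philips") {
    calibration <- calibrate_philips(seq$frames[[1]],
                                     spacing_cm = marker_spacing_cm)
  } else if (calib_mode == "ge") {
    calibration <- calibrate_ge(seq$frames[[1]],
                                line_length_cm = marker_spacing_cm)
  } else if (is.null(calibration)) {
    stop_calibration("explicit calibration mode requires a pixel_calibration")
  }

  scan <- threshold_scan(seq, calibration, t_min = t_min, t_max = t_max,
                         perimeter_jump_cm = perimeter_jump_cm)
  grade <- classify_mva(scan$mva_cm2)

  report <- structure(
    list(video = video_path, calibration = calibration, scan = scan,
         mva_cm2 = scan$mva_cm2, grade = grade,
         selected_frame_index = scan$selected_frame_index,
         report_path = NULL, overlay_path = NULL),
    class = "dip_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- tools::file_path_sans_ext(basename(video_path))
    report$report_path <- file.path(out_dir, paste0(stem, "_dip.json"))
    jsonlite::write_json(
      list(video = video_path,
           cm_per_px_x = calibration$cm_per_px_x,
           cm_per_px_y = calibration$cm_per_px_y,
           selected_threshold = scan$selected_threshold,
           selected_frame_index = scan$selected_frame_index,
           mva_cm2 = scan$mva_cm2,
           grade = as.character(grade),
           stop_reason = scan$stop_reason,
           records = dplyr::select(scan$records, -"contour")),
      report$report_path, auto_unbox = TRUE, digits = NA)
    report$overlay_path <- file.path(out_dir, paste0(stem, "_overlay.png"))
    sel <- which(scan$records$threshold == scan$selected_threshold)
    save_contour_overlay(seq$frames[[scan$selected_frame_index]],
                         scan$records$contour[[sel]],
                         scan$mva_cm2, report$overlay_path)
  }
  report
}

#' @export
print.dip_report <- function(x, ...) {
  cat(sprintf(
    "<dip_report: %s>\n  MVA %.3f cm2 at threshold %d (frame %d) -> %s\n",
    basename(x$video), x$mva_cm2, x$scan$selected_threshold,
    x$selected_frame_index, as.character(x$grade)))
  invisible(x)
}

#' Save a frame with the orifice contour overlaid
#'
#' Draws the boundary as a solid white line over the frame and prints the
#' measured area in the corner.
#'
#' @param frame RGB frame array
#' @param contour an `orifice_contour` (or `NULL` for no overlay)
#' @param area_cm2 area annotation, cm^2
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
save_contour_overlay <- function(frame, contour, area_cm2, path) {
  fr <- frame
  if (!is.null(contour)) {
    b <- contour$boundary
    for (ch in 1:3) {
      plane <- fr[, , ch]
      plane[cbind(b[, 1], b[, 2])] <- 255L
      fr[, , ch] <- plane
    }
  }
  h <- dim(fr)[1]; w <- dim(fr)[2]
  grDevices::png(path, width = w, height = h, type = "cairo")
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(0, h), xaxs = "i", yaxs = "i")
  graphics::rasterImage(grDevices::as.raster(fr / 255), 0, 0, w, h,
                        interpolate = FALSE)
  graphics::text(5, h - 10, sprintf("Area = %.2f cm2", area_cm2),
                 col = "white", adj = c(0, 1))
  invisible(path)
}

#' Compare the planimetry and CNN verdicts on one video
#'
#' Runs both arms and reports them side by side: the planimetry arm yields
#' the measured area, its contour and a four-level severity grade (reduced
#' to has/no stenosis for comparison); the CNN yields only a binary verdict.
#' Disagreements are flagged.
#'
#' @param video_path path to an AVI video
#' @param model a trained `cnn_model` or `cnn_fit`
#' @param ... passed on to [run_dip()]
#' @return object of class `comparison_report`: `dip` (the `dip_report`),
#'   `cnn` (the `video_prediction`), `dip_verdict`, `cnn_verdict`, `agree`
#' @export
run_compare <- function(video_path, model, ...) {
  dip <- run_dip(video_path, ...)
  cnn <- predict_video(model, video_path)
  dip_verdict <- factor(
    if (dip$grade == "no_stenosis") "no_stenosis" else "has_stenosis",
    levels = class_levels())
  structure(
    list(dip = dip, cnn = cnn,
         dip_verdict = dip_verdict, cnn_verdict = cnn$verdict,
         agree = dip_verdict == cnn$verdict),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report: DIP %s (grade %s, MVA %.2f cm2) vs CNN %s -> %s>\n",
    as.character(x$dip_verdict), as.character(x$dip$grade), x$dip$mva_cm2,
    as.character(x$cnn_verdict),
    if (x$agree) "agreement" else "DISAGREEMENT"))
  invisible(x)
}
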