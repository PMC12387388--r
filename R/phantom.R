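# Synthetic echocardiogram-like phantom videos with known ground truth.
#
# A phantom emulates what the planimetry engine actually relies on in a 3D
# TEE en-face render: bright multi-coloured tissue surrounding a central dark
# orifice whose area follows the cardiac cycle, a dark background touching
# the image border, vendor calibration markers, and optional speckle-like
# channel noise. A lower-echogenicity annulus ring whose radius tracks the
# diastolic orifice size is rendered in every frame: real renders show the
# valve apparatus throughout the cycle (which is why the screening CNN is
# trained on all frames), and the ring's luminance (~69) stays above every
# scan threshold so the planimetry engine never sees it.

#' Specify a synthetic echocardiogram phantom
#'
#' @param size image side length in pixels (square frames)
#' @param n_frames number of frames covering one open-close cycle
#' @param diastolic_mva_cm2 ground-truth maximum orifice area, cm^2; 0 keeps
#'   the valve closed throughout
#' @param peak_frame frame index of the diastolic maximum (default: middle)
#' @param orifice_shape `"ellipse"` (axis ratio 1.25) or `"blob"` (ellipse
#'   with a smooth angular radius perturbation)
#' @param tissue_palette list of RGB triplets used for the tissue sectors;
#'   all default colours have luminance well above the scan's top threshold
#' @param noise_sigma sd of additive Gaussian channel noise, clipped to
#'   `[0, 255]` (default 8: exercises, but does not defeat, the scan)
#' @param marker_dialect `"philips"` (green ruler dots), `"ge"` (scale line)
#'   or `"none"`
#' @param cm_per_px true isotropic pixel size (default 0.025 cm)
#' @param marker_spacing_cm physical spacing of the philips dots / length of
#'   the ge line (default 1.0 cm)
#' @param seed integer RNG seed making the rendering deterministic
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(size = 192L, n_frames = 40L, diastolic_mva_cm2 = 2.5,
                         peak_frame = NULL,
                         orifice_shape = c("ellipse", "blob"),
                         tissue_palette = NULL, noise_sigma = 8,
                         marker_dialect = c("philips", "ge", "none"),
                         cm_per_px = 0.025, marker_spacing_cm = 1.0,
                         seed = 1L) {
  orifice_shape <- match.arg(orifice_shape)
  marker_dialect <- match.arg(marker_dialect)
  size <- as.integer(size); n_frames <- as.integer(n_frames)
  if (size < 64L) stop_validation("phantom size must be at least 64 px")
  if (n_frames < 1L) stop_validation("n_frames must be >= 1")
  if (diastolic_mva_cm2 < 0) stop_validation("diastolic_mva_cm2 must be >= 0")
  if (cm_per_px <= 0) stop_validation("cm_per_px must be positive")
  if (is.null(peak_frame)) peak_frame <- max(1L, n_frames %/% 2L)
  peak_frame <- as.integer(peak_frame)
  if (peak_frame < 1L || peak_frame > n_frames)
    stop_validation("peak_frame must index a frame")
  if (is.null(tissue_palette)) {
    tissue_palette <- list(c(205L, 112L, 92L), c(222L, 150L, 80L),
                           c(238L, 185L, 60L), c(190L, 120L, 150L))
  }
  structure(
    list(size = size, n_frames = n_frames,
         diastolic_mva_cm2 = diastolic_mva_cm2, peak_frame = peak_frame,
         orifice_shape = orifice_shape, tissue_palette = tissue_palette,
         noise_sigma = noise_sigma, marker_dialect = marker_dialect,
         cm_per_px = cm_per_px, marker_spacing_cm = marker_spacing_cm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# raised-cosine open-close trajectory: 0 at the first and last frame,
# 1 at the peak frame
phantom_trajectory <- function(n_frames, peak_frame) {
  if (n_frames == 1L) return(1)
  f <- seq_len(n_frames)
  t <- numeric(n_frames)
  if (peak_frame > 1L)
    t[f <= peak_frame] <- 0.5 * (f[f <= peak_frame] - 1) / (peak_frame - 1)
  else t[1] <- 0.5
  if (peak_frame < n_frames)
    t[f > peak_frame] <- 0.5 + 0.5 * (f[f > peak_frame] - peak_frame) /
      (n_frames - peak_frame)
  0.5 * (1 - cos(2 * pi * t))
}

#' Render a phantom video in memory
#'
#' Deterministic for a fixed spec (including its seed). Ground-truth
#' per-frame orifice areas are measured from the rendered orifice mask
#' itself (pixel count times pixel area), so rasterisation is accounted for.
#'
#' @param spec a [phantom_spec()]
#' @return list with `frames` (a `frame_sequence`) and `truth` (class
#'   `phantom_truth`: `frame_areas_cm2`, `max_area_cm2`, `peak_frame`,
#'   `calibration`, `spec`)
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  s <- spec$size
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  pixel_area <- spec$cm_per_px^2

  # geometry: tissue disk, max orifice ellipse, annulus ring
  tissue_r <- 0.40 * s
  a_ratio <- 1.25
  max_area_px <- spec$diastolic_mva_cm2 / pixel_area
  r0 <- sqrt(max_area_px / pi)
  a_max <- r0 * sqrt(a_ratio); b_max <- r0 / sqrt(a_ratio)
  if (a_max > tissue_r - 6)
    stop_validation("orifice larger than the tissue region; increase size or cm_per_px")

  xs <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
  ys <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
  dx <- xs - cx; dy <- ys - cy
  rr <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)

  tissue <- rr <= tissue_r
  # angular blob perturbation, fixed across frames so areas stay analytic
  blob_mod <- if (spec$orifice_shape == "blob") {
    ph <- runif(2, 0, 2 * pi)
    1 + 0.15 * sin(3 * ang + ph[1]) + 0.08 * sin(5 * ang + ph[2])
  } else 1

  # base tissue colouring: angular sectors with radial brightness ripple
  sector <- (floor((ang + pi) / (2 * pi) * 8) %% length(spec$tissue_palette)) + 1
  ripple <- 1 - 0.12 * (0.5 + 0.5 * sin(rr / 6))
  base <- array(0L, dim = c(s, s, 3))
  pal <- do.call(rbind, spec$tissue_palette)
  for (ch in 1:3) {
    plane <- matrix(0, s, s)
    plane[tissue] <- pal[sector[tissue], ch] * ripple[tissue]
    base[, , ch] <- as.integer(round(plane))
  }

  # annulus ring cue at the diastolic orifice radius, luminance ~69
  if (spec$diastolic_mva_cm2 > 0) {
    ell <- sqrt((dx / a_max)^2 + (dy / b_max)^2) / blob_mod
    ring <- tissue & ell >= 1.0 & ell <= 1.18
    base[, , 1][ring] <- 90L
    base[, , 2][ring] <- 60L
    base[, , 3][ring] <- 60L
  }

  # vendor markers
  if (spec$marker_dialect == "philips") {
    gap <- max(2L, as.integer(round(spec$marker_spacing_cm / spec$cm_per_px)))
    xm <- s - 8L
    ym <- seq(10L, s - 4L, by = gap)
    for (y in ym) {
      rows <- pmin(s, pmax(1L, y + (-1L:1L)))
      cols <- pmin(s, pmax(1L, xm + (-1L:1L)))
      base[rows, cols, 1] <- 0L
      base[rows, cols, 2] <- 220L
      base[rows, cols, 3] <- 0L
    }
  } else if (spec$marker_dialect == "ge") {
    len <- max(2L, as.integer(round(spec$marker_spacing_cm / spec$cm_per_px)))
    row <- s - 8L
    cols <- (s - 6L - len + 1L):(s - 6L)
    base[row + 0:1, cols, ] <- 255L
  }

  traj <- phantom_trajectory(spec$n_frames, spec$peak_frame)
  frames <- vector("list", spec$n_frames)
  areas <- numeric(spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    fr <- base
    if (spec$diastolic_mva_cm2 > 0 && traj[i] > 0) {
      af <- a_max * sqrt(traj[i]); bf <- b_max * sqrt(traj[i])
      open_px <- tissue &
        (sqrt((dx / af)^2 + (dy / bf)^2) / blob_mod) < 1.0
      for (ch in 1:3) fr[, , ch][open_px] <- 0L
      areas[i] <- sum(open_px) * pixel_area
    }
    if (spec$noise_sigma > 0) {
      noise <- array(rnorm(length(fr), 0, spec$noise_sigma), dim = dim(fr))
      fr <- array(as.integer(pmin(255, pmax(0, round(fr + noise)))),
                  dim = dim(fr))
    }
    frames[[i]] <- fr
  }

  dialect <- if (spec$marker_dialect == "none") "explicit" else spec$marker_dialect
  truth <- structure(
    list(frame_areas_cm2 = areas,
         max_area_cm2 = max(areas),
         peak_frame = if (all(areas == 0)) NA_integer_ else which.max(areas),
         calibration = explicit_calibration(spec$cm_per_px),
         spec = spec),
    class = "phantom_truth"
  )
  list(frames = frame_sequence(frames, vendor_dialect = dialect),
       truth = truth)
}

#' Generate a phantom AVI video on disk
#'
#' Renders the phantom and writes it with the package's lossless AVI writer;
#' running the same spec twice produces byte-identical files.
#'
#' @param spec a [phantom_spec()]
#' @param path output `.avi` path
#' @param truth_path optional path for a JSON dump of the ground truth
#' @return list with `video` (path) and `truth` (a `phantom_truth`)
#' @export
generate_phantom <- function(spec, path, truth_path = NULL) {
  rendered <- render_phantom(spec)
  write_avi(rendered$frames, path)
  if (!is.null(truth_path)) {
    tr <- rendered$truth
    jsonlite::write_json(
      list(frame_areas_cm2 = tr$frame_areas_cm2,
           max_area_cm2 = tr$max_area_cm2,
           peak_frame = tr$peak_frame,
           cm_per_px = tr$spec$cm_per_px,
           seed = tr$spec$seed),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(video = path, truth = rendered$truth))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth: %d frame(s), max area %.4f cm2 at frame %s, %.3g cm/px>\n",
    length(x$frame_areas_cm2), x$max_area_cm2,
    ifelse(is.na(x$peak_frame), "none", x$peak_frame),
    x$calibration$cm_per_px_x))
  invisible(x)
}

#' Generate a labelled cohort of phantom videos
#'
#' Samples ground-truth diastolic MVAs uniformly inside each severity grade's
#' interval (inset slightly from the interval endpoints so rasterisation
#' cannot flip a grade) and writes one phantom video per draw. Intended as
#' the stand-in training/testing corpus for the screening CNN.
#'
#' @param n_per_grade videos per grade: a single count, or a named vector
#'   with entries `no_stenosis`, `mild`, `moderate`, `severe`
#' @param seed integer seed controlling both the MVA draws and the rendering
#' @param dir output directory for the `.avi` files (default: a fresh tempdir)
#' @param n_frames,size,noise_sigma,marker_dialect,cm_per_px passed to
#'   [phantom_spec()]
#' @return tibble with columns `video` (path), `mva_cm2` (sampled truth),
#'   `grade`, `label` (`has_stenosis`/`no_stenosis`), `truth` (list column of
#'   `phantom_truth`)
#' @export
generate_cohort <- function(n_per_grade, seed = 1L, dir = NULL,
                            n_frames = 16L, size = 192L, noise_sigma = 8,
                            marker_dialect = "philips", cm_per_px = 0.025) {
  if (is.null(dir)) dir <- tempfile("phantom_cohort_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grades <- grade_levels()
  if (length(n_per_grade) == 1L && is.null(names(n_per_grade)))
    n_per_grade <- stats::setNames(rep(as.integer(n_per_grade), 4L), grades)
  if (!all(grades %in% names(n_per_grade)))
    stop_validation("n_per_grade must be a single count or name all four grades")
  if (any(n_per_grade[grades] < 0L)) stop_validation("counts must be >= 0")

  # sampling intervals, inset ~5% from the clinical cutoffs
  intervals <- list(no_stenosis = c(4.2, 6.0), mild = c(1.65, 3.85),
                    moderate = c(1.03, 1.47), severe = c(0.30, 0.95))
  set.seed(seed)
  rows <- list()
  counter <- 0L
  for (g in grades) {
    for (i in seq_len(n_per_grade[[g]])) {
      counter <- counter + 1L
      mva <- runif(1, intervals[[g]][1], intervals[[g]][2])
      sp <- phantom_spec(size = size, n_frames = n_frames,
                         diastolic_mva_cm2 = mva,
                         noise_sigma = noise_sigma,
                         marker_dialect = marker_dialect,
                         cm_per_px = cm_per_px,
                         seed = (abs(seed) %% 1000000L) * 1000L + counter)
      path <- file.path(dir, sprintf("%s_%03d.avi", g, counter))
      out <- generate_phantom(sp, path)
      rows[[counter]] <- tibble(
        video = path, mva_cm2 = mva,
        grade = factor(g, levels = grades),
        label = factor(if (g == "no_stenosis") "no_stenosis" else "has_stenosis",
                       levels = class_levels()),
        truth = list(out$truth))
    }
  }
  bind_rows(rows)
}
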