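# Independent pure-R oracles used to check the C++-backed planimetry path.

# stack a gray matrix into an RGB frame (v, v, v)
gray_rgb_frame <- function(m) {
  array(as.integer(m), dim = c(nrow(m), ncol(m), 3))
}

# flood fill over TRUE pixels from a set of seed indices (4-connected);
# returns a logical matrix of reached pixels. Queue-based, no C++.
r_flood_reach <- function(open, seeds) {
  nr <- nrow(open); nc <- ncol(open)
  reached <- matrix(FALSE, nr, nc)
  queue <- seeds[open[seeds]]
  reached[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[length(queue)]
    queue <- queue[-length(queue)]
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
          open[rr, cc] && !reached[rr, cc]) {
        reached[rr, cc] <- TRUE
        queue <- c(queue, rr + (cc - 1L) * nr)
      }
    }
  }
  reached
}

# oracle for the enclosed-orifice rule: label 4-connected dark regions in R,
# drop those reaching the border, return the pixel count of the largest
# (0 when none exists)
r_orifice_pixels <- function(mask) {
  dark <- mask == 0L
  nr <- nrow(dark); nc <- ncol(dark)
  border <- unique(c(seq_len(nr), seq_len(nr) + (nc - 1L) * nr,
                     1L + (seq_len(nc) - 1L) * nr, nr + (seq_len(nc) - 1L) * nr))
  background <- r_flood_reach(dark, border)
  enclosed <- dark & !background
  if (!any(enclosed)) return(0L)
  # count pixels of the largest 4-connected enclosed region
  best <- 0L
  remaining <- enclosed
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- r_flood_reach(remaining, seed)
    best <- max(best, sum(comp))
    remaining <- remaining & !comp
  }
  best
}

# brute-force version of the threshold scan: evaluate every threshold
# independently, then apply the stop rule post hoc
r_scan_oracle <- function(seq, calibration, t_min = 10L, t_max = 30L,
                          jump = 1.0) {
  recs <- lapply(t_min:t_max, function(t)
    max_opening_frame(seq, t, calibration))
  recs <- do.call(rbind, recs)
  stop_at <- NA_integer_
  for (i in 2:nrow(recs)) {
    if (abs(recs$perimeter_cm[i] - recs$perimeter_cm[i - 1]) > jump) {
      stop_at <- i
      break
    }
  }
  if (is.na(stop_at)) {
    list(selected_threshold = recs$threshold[nrow(recs)],
         selected_frame_index = recs$best_frame_index[nrow(recs)],
         mva_cm2 = recs$area_cm2[nrow(recs)],
         stop_reason = "threshold_cap", n_visited = nrow(recs))
  } else {
    list(selected_threshold = recs$threshold[stop_at - 1L],
         selected_frame_index = recs$best_frame_index[stop_at - 1L],
         mva_cm2 = recs$area_cm2[stop_at - 1L],
         stop_reason = "perimeter_jump", n_visited = stop_at)
  }
}

# small phantom settings used throughout the tests (cm_per_px enlarged so
# big orifices still fit a small raster)
small_phantom <- function(mva, seed = 1L, noise_sigma = 0, n_frames = 8L,
                          size = 96L, ...) {
  phantom_spec(size = size, n_frames = n_frames, diastolic_mva_cm2 = mva,
               noise_sigma = noise_sigma, cm_per_px = 0.05, seed = seed, ...)
}
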