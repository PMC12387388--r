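test_that("grayscale conversion applies the luminance weights with half-up rounding", {
  fr <- array(0L, dim = c(1, 4, 3))
  fr[1, 1, ] <- c(0L, 0L, 0L)
  fr[1, 2, ] <- c(255L, 255L, 255L)  # 254.9745 -> 255
  fr[1, 3, ] <- c(100L, 100L, 100L)  # 99.99 -> 100
  fr[1, 4, ] <- c(10L, 200L, 30L)    # 2.989 + 117.4 + 3.42 = 123.809 -> 124
  g <- to_grayscale(fr)
  expect_identical(as.vector(g), c(0L, 255L, 100L, 124L))
})

test_that("binarization is strict and rejects out-of-range thresholds", {
  gray <- matrix(c(21L, 20L, 19L, 0L, 255L, 20L), nrow = 2)
  out <- binarize(gray, 20)
  expect_identical(as.vector(out), c(1L, 0L, 0L, 0L, 1L, 0L))
  expect_error(binarize(gray, 0), class = "echoplanim_validation_error")
  expect_error(binarize(gray, 255), class = "echoplanim_validation_error")
})

test_that("raising the threshold only ever shrinks the bright set", {
  set.seed(81)
  for (rep in 1:5) {
    gray <- matrix(sample(0:60, 40 * 40, replace = TRUE), 40)
    prev <- binarize(gray, 10)
    for (t in 11:30) {
      cur <- binarize(gray, t)
      expect_true(all(cur <= prev),
                  info = sprintf("rep %d threshold %d", rep, t))
      prev <- cur
    }
  }
})

test_that("a square hole yields the hand-computed area and perimeter", {
  mask <- matrix(1L, 30, 30)
  mask[11:20, 11:20] <- 0L
  cal <- explicit_calibration(0.1, 0.1)
  ct <- find_orifice_contour(mask, cal)
  expect_s3_class(ct, "orifice_contour")
  expect_identical(ct$interior_pixel_count, 100L)
  expect_equal(ct$area_cm2, 1.0)
  # boundary through pixel centres of a 10x10 ring: 4 sides of 9 steps
  expect_equal(ct$perimeter_cm, 4 * 9 * 0.1)
  expect_identical(ct$interior_pixel_count, r_orifice_pixels(mask))
})

test_that("masks without an enclosed dark region yield no orifice", {
  cal <- explicit_calibration(0.1)
  expect_null(find_orifice_contour(matrix(1L, 20, 20), cal))
  # dark region touching the border is background, not orifice
  mask <- matrix(1L, 20, 20)
  mask[1:6, 8:12] <- 0L
  expect_null(find_orifice_contour(mask, cal))
  expect_identical(r_orifice_pixels(mask), 0L)
})

test_that("the largest of several enclosed dark regions is measured", {
  mask <- matrix(1L, 40, 40)
  mask[5:8, 5:8] <- 0L      # 16 px
  mask[20:29, 20:29] <- 0L  # 100 px
  cal <- explicit_calibration(0.05)
  ct <- find_orifice_contour(mask, cal)
  expect_identical(ct$interior_pixel_count, 100L)
  expect_identical(ct$interior_pixel_count, r_orifice_pixels(mask))
})

test_that("orifice pixel counts agree with the flood-fill oracle on random masks", {
  set.seed(19)
  cal <- explicit_calibration(0.1)
  for (rep in 1:8) {
    gray <- matrix(sample(0:40, 25 * 25, replace = TRUE), 25)
    mask <- binarize(gray, 20)
    ct <- find_orifice_contour(mask, cal)
    got <- if (is.null(ct)) 0L else ct$interior_pixel_count
    expect_identical(got, r_orifice_pixels(mask), info = paste("rep", rep))
  }
})

test_that("areas scale with the square of the calibration, perimeters linearly", {
  ph <- render_phantom(small_phantom(1.5, seed = 9, n_frames = 4L))
  mask <- binarize(to_grayscale(ph$frames$frames[[2]]), 20)
  cal1 <- explicit_calibration(0.05)
  cal3 <- explicit_calibration(0.15)
  ct1 <- find_orifice_contour(mask, cal1)
  ct3 <- find_orifice_contour(mask, cal3)
  expect_equal(ct3$area_cm2, 9 * ct1$area_cm2)
  expect_equal(ct3$perimeter_cm, 3 * ct1$perimeter_cm)
})

test_that("max_opening_frame finds the diastolic peak and breaks ties early", {
  ph <- render_phantom(small_phantom(2.0, seed = 4, n_frames = 9L))
  cal <- ph$truth$calibration
  rec <- max_opening_frame(ph$frames, 20, cal)
  expect_equal(rec$best_frame_index, ph$truth$peak_frame)
  expect_equal(rec$area_cm2, ph$truth$max_area_cm2)

  # two identical frames tied for the maximum -> earliest index wins
  fr <- gray_rgb_frame({
    m <- matrix(200L, 30, 30)
    m[14:17, 14:17] <- 0L
    m
  })
  closed <- gray_rgb_frame(matrix(200L, 30, 30))
  seq2 <- frame_sequence(list(closed, fr, fr))
  rec2 <- max_opening_frame(seq2, 20, cal)
  expect_identical(rec2$best_frame_index, 2L)

  # all-closed sequence scores zero area and perimeter
  rec3 <- max_opening_frame(frame_sequence(list(closed)), 20, cal)
  expect_equal(rec3$area_cm2, 0)
  expect_equal(rec3$perimeter_cm, 0)
})

test_that("threshold_scan stops on an engineered perimeter jump at t = 17", {
  # tissue at 200, orifice disk, and a moat ring of gray 17: bright for
  # t < 17, dark from t = 17 on, when the enclosed dark region suddenly
  # becomes the much larger ring -> perimeter jump > 1 cm
  m <- matrix(200L, 60, 60)
  cx <- 30.5
  d <- sqrt(outer((1:60 - cx)^2, (1:60 - cx)^2, "+"))
  m[d < 8] <- 0L
  m[d >= 16 & d <= 20] <- 17L
  seqs <- frame_sequence(list(gray_rgb_frame(m)))
  cal <- explicit_calibration(0.05)
  scan <- threshold_scan(seqs, cal)
  expect_identical(scan$stop_reason, "perimeter_jump")
  expect_identical(scan$selected_threshold, 16L)
  expect_identical(max(scan$records$threshold), 17L)
  # the selected area is the small disk, not the moat
  expect_equal(scan$mva_cm2, sum(d < 8) * 0.0025)

  oracle <- r_scan_oracle(seqs, cal)
  expect_identical(scan$selected_threshold, oracle$selected_threshold)
  expect_equal(scan$mva_cm2, oracle$mva_cm2)
})

test_that("threshold_scan equals the brute-force oracle on phantoms", {
  cases <- list(
    list(mva = 0.8, noise = 0, seed = 21),
    list(mva = 2.5, noise = 8, seed = 22),
    list(mva = 4.5, noise = 8, seed = 23))
  for (cs in cases) {
    ph <- render_phantom(small_phantom(cs$mva, seed = cs$seed,
                                       noise_sigma = cs$noise, n_frames = 6L))
    cal <- ph$truth$calibration
    scan <- threshold_scan(ph$frames, cal)
    oracle <- r_scan_oracle(ph$frames, cal)
    expect_identical(scan$selected_threshold, oracle$selected_threshold)
    expect_identical(scan$selected_frame_index, oracle$selected_frame_index)
    expect_equal(scan$mva_cm2, oracle$mva_cm2)
    expect_identical(scan$stop_reason, oracle$stop_reason)
    expect_identical(nrow(scan$records), oracle$n_visited)
  }
})

test_that("threshold_scan validates its inputs", {
  cal <- explicit_calibration(0.05)
  ph <- render_phantom(small_phantom(1.0, seed = 2, n_frames = 2L))
  expect_error(threshold_scan(ph$frames, cal, t_min = 20, t_max = 10),
               class = "echoplanim_validation_error")
  expect_error(threshold_scan(ph$frames, cal, t_min = 0),
               class = "echoplanim_validation_error")
})

test_that("scan results expose tidy records and a one-row summary", {
  ph <- render_phantom(small_phantom(2.5, seed = 6, n_frames = 6L))
  scan <- threshold_scan(ph$frames, ph$truth$calibration)
  td <- tidy(scan)
  expect_named(td, c("threshold", "best_frame_index", "area_cm2",
                     "perimeter_cm"))
  expect_identical(nrow(td), nrow(scan$records))
  gl <- glance(scan)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$mva_cm2, scan$mva_cm2)
  expect_identical(as.character(gl$grade), "mild")
  p <- ggplot2::autoplot(scan)
  expect_s3_class(p, "ggplot")
})
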