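test_that("AVI round trip is lossless for phantom frames", {
  ph <- render_phantom(small_phantom(1.2, seed = 5, noise_sigma = 8,
                                     n_frames = 6L))
  path <- withr::local_tempfile(fileext = ".avi")
  write_avi(ph$frames, path)
  back <- extract_frames(path, vendor_dialect = "philips")
  expect_length(back$frames, 6L)
  expect_equal(back$vendor_dialect, "philips")
  for (i in seq_along(back$frames))
    expect_identical(back$frames[[i]], unclass(ph$frames$frames[[i]]))
})

test_that("a one-frame AVI and odd widths survive the container", {
  # width 37: row stride needs padding to a 4-byte boundary
  fr <- array(sample.int(256, 21 * 37 * 3, replace = TRUE) - 1L,
              dim = c(21, 37, 3))
  path <- withr::local_tempfile(fileext = ".avi")
  write_avi(list(fr), path)
  back <- extract_frames(path)
  expect_length(back$frames, 1L)
  expect_identical(back$frames[[1]], fr)
})

test_that("unreadable inputs raise I/O errors", {
  expect_error(extract_frames(file.path(tempdir(), "absent.avi")),
               class = "echoplanim_io_error")
  fake <- withr::local_tempfile(fileext = ".avi")
  writeLines("this is not a video", fake)
  expect_error(extract_frames(fake), class = "echoplanim_io_error")
})

test_that("philips green-dot calibration matches its defining ratio", {
  blank <- array(0L, dim = c(120, 120, 3))
  put_dot <- function(fr, r, c) {
    fr[r + (-1:1), c + (-1:1), 2] <- 220L
    fr
  }
  # two dots 50 px apart vertically, spacing 1.0 cm -> 0.02 cm/px
  fr <- put_dot(put_dot(blank, 30, 100), 80, 100)
  cal <- calibrate_philips(fr, spacing_cm = 1.0)
  expect_equal(cal$cm_per_px_x, 0.02)
  expect_equal(cal$cm_per_px_y, 0.02)
  expect_equal(cal$pixel_area_cm2, 4e-4)

  # dots 25 px apart, spacing 0.5 cm -> same pixel size
  fr2 <- put_dot(put_dot(blank, 30, 100), 55, 100)
  cal2 <- calibrate_philips(fr2, spacing_cm = 0.5)
  expect_equal(cal2$cm_per_px_x, 0.02)

  # scale equivariance: doubling the dot distance halves cm/px exactly
  fr3 <- put_dot(put_dot(blank, 10, 100), 110, 100)
  cal3 <- calibrate_philips(fr3, spacing_cm = 1.0)
  expect_equal(cal3$cm_per_px_x, cal$cm_per_px_x / 2)
})

test_that("philips calibration fails without two green dots", {
  blank <- array(0L, dim = c(60, 60, 3))
  expect_error(calibrate_philips(blank),
               class = "echoplanim_calibration_error")
  one <- blank
  one[20:22, 20:22, 2] <- 220L
  expect_error(calibrate_philips(one),
               class = "echoplanim_calibration_error")
})

test_that("ge scale-line calibration uses the line extent", {
  blank <- array(0L, dim = c(200, 200, 3))
  fr <- blank
  fr[180, 61:160, ] <- 255L  # 100 px long, bright white
  cal <- calibrate_ge(fr, region = c(101, 200, 1, 200), line_length_cm = 1.0)
  expect_equal(cal$cm_per_px_x, 0.01)
  expect_equal(cal$cm_per_px_y, 0.01)

  fr2 <- blank
  fr2[190, 150:189, ] <- 255L  # 40 px, configured 2.0 cm -> 0.05 cm/px
  cal2 <- calibrate_ge(fr2, line_length_cm = 2.0)
  expect_equal(cal2$cm_per_px_x, 0.05)

  expect_error(calibrate_ge(blank), class = "echoplanim_calibration_error")
})

test_that("explicit calibration validates and multiplies factors", {
  cal <- explicit_calibration(0.01, 0.01)
  expect_equal(cal$pixel_area_cm2, 1e-4)
  cal2 <- explicit_calibration(0.02, 0.01)
  expect_equal(cal2$pixel_area_cm2, 2e-4)
  expect_error(explicit_calibration(0, 0.01),
               class = "echoplanim_validation_error")
  expect_error(explicit_calibration(-1), class = "echoplanim_validation_error")
})
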