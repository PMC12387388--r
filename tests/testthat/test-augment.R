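test_that("augment_frame honours the count and the identity transform", {
  fr <- render_phantom(small_phantom(1.0, seed = 2, n_frames = 1L))$frames$frames[[1]]
  cfg <- augmentation_config(n_aug_per_frame = 6L, seed = 4L)
  out <- augment_frame(fr, cfg)
  expect_length(out, 6L)
  expect_true(all(vapply(out, function(x) identical(dim(x), dim(fr)),
                         logical(1))))
  # some geometric change must actually have happened
  expect_false(identical(out[[1]], fr))

  ident <- augmentation_config(rotation_range = 0, width_shift = 0,
                               height_shift = 0, shear_range = 0,
                               zoom_range = 0, horizontal_flip = FALSE,
                               n_aug_per_frame = 3L)
  copies <- augment_frame(fr, ident)
  for (cp in copies) expect_identical(cp, unclass(fr))
})

test_that("a seeded augmentation call is deterministic", {
  fr <- render_phantom(small_phantom(2.0, seed = 3, n_frames = 1L))$frames$frames[[1]]
  cfg <- augmentation_config(n_aug_per_frame = 4L, seed = 99L)
  expect_identical(augment_frame(fr, cfg), augment_frame(fr, cfg))
})

test_that("augmented corpora carry class-prefixed unique names and labels", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(1L, seed = 8L, dir = dir, n_frames = 2L, size = 96L, cm_per_px = 0.05,
                        noise_sigma = 0)
  imgs <- augment_videos(co, augmentation_config(n_aug_per_frame = 2L),
                         seed = 1L)
  # 4 videos x 2 frames x (1 original + 2 augmented)
  expect_identical(nrow(imgs), 24L)
  expect_false(any(duplicated(imgs$filename)))
  expect_true(all(startsWith(imgs$filename, as.character(imgs$label))))
  # augmented copies keep the source frame's label
  expect_identical(unique(imgs$label[imgs$augmented]),
                   unique(imgs$label[!imgs$augmented]))
})

test_that("split_dataset conserves images and excludes holdout videos", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(no_stenosis = 3L, mild = 1L, moderate = 1L,
                          severe = 1L),
                        seed = 10L, dir = dir, n_frames = 2L, size = 96L, cm_per_px = 0.05,
                        noise_sigma = 0)
  imgs <- augment_videos(co, augmentation_config(n_aug_per_frame = 1L),
                         seed = 2L)
  sp <- split_dataset(imgs, test_fraction = 0.3, holdout_videos = 1L,
                      seed = 3L)
  held_frames <- sum(imgs$video_id %in% sp$holdout)
  expect_identical(nrow(sp$train) + nrow(sp$test),
                   nrow(imgs) - held_frames)
  expect_length(sp$holdout, 2L)
  expect_false(any(sp$train$video_id %in% sp$holdout))
  expect_false(any(sp$test$video_id %in% sp$holdout))
  # per-class test fraction holds up to integer rounding
  for (cl in c("has_stenosis", "no_stenosis")) {
    pool_n <- sum(!(imgs$video_id %in% sp$holdout) & imgs$label == cl)
    expect_equal(sum(sp$test$label == cl), round(0.3 * pool_n))
  }
})

test_that("degenerate splits behave and missing classes are rejected", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(no_stenosis = 1L, mild = 1L, moderate = 0L,
                          severe = 0L),
                        seed = 12L, dir = dir, n_frames = 2L, size = 96L, cm_per_px = 0.05,
                        noise_sigma = 0)
  imgs <- augment_videos(co, augmentation_config(n_aug_per_frame = 1L),
                         seed = 4L)
  sp0 <- split_dataset(imgs, test_fraction = 0, holdout_videos = 0L, seed = 5L)
  expect_identical(nrow(sp0$test), 0L)
  expect_identical(nrow(sp0$train), nrow(imgs))
  one_class <- imgs[imgs$label == "has_stenosis", ]
  expect_error(split_dataset(one_class, 0.3, 0L, 1L),
               class = "echoplanim_validation_error")
})

test_that("augmentation config validates its ranges", {
  expect_error(augmentation_config(rotation_range = -1),
               class = "echoplanim_validation_error")
  expect_error(augmentation_config(width_shift = 1.5),
               class = "echoplanim_validation_error")
  expect_error(augmentation_config(fill_mode = "reflect"),
               class = "echoplanim_validation_error")
})
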