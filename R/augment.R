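#' Configure the image augmentation recipe
#'
#' The recipe used to expand the frame corpus: random rotations within
#' `rotation_range` degrees, horizontal/vertical shifts of up to
#' `width_shift`/`height_shift` of the image size, random shear and zoom,
#' and a fair-coin horizontal flip; pixels exposed by a transform are filled
#' by nearest-neighbour (edge replication). Six additional images per frame
#' is the default expansion factor.
#'
#' @param rotation_range max absolute rotation, degrees (default 40)
#' @param width_shift,height_shift max absolute shift as a fraction of the
#'   image width/height (default 0.2)
#' @param shear_range max absolute shear angle, radians (default 0.2,
#'   about 11 degrees)
#' @param zoom_range max relative zoom, so the scale is drawn from
#'   `[1 - zoom_range, 1 + zoom_range]` (default 0.2)
#' @param horizontal_flip flip with probability 1/2 when `TRUE`
#' @param fill_mode only `"nearest"` is supported
#' @param n_aug_per_frame augmented images generated per input frame
#' @param seed optional seed fixed at the start of each [augment_frame()]
#'   call, making the call deterministic
#' @return object of class `augmentation_config`
#' @export
augmentation_config <- function(rotation_range = 40, width_shift = 0.2,
                                height_shift = 0.2, shear_range = 0.2,
                                zoom_range = 0.2, horizontal_flip = TRUE,
                                fill_mode = "nearest", n_aug_per_frame = 6L,
                                seed = NULL) {
  if (rotation_range < 0) stop_validation("rotation_range must be >= 0")
  if (width_shift < 0 || width_shift > 1 || height_shift < 0 || height_shift > 1)
    stop_validation("shifts must lie in [0, 1]")
  if (n_aug_per_frame < 0) stop_validation("n_aug_per_frame must be >= 0")
  if (!identical(fill_mode, "nearest"))
    stop_validation("only fill_mode = 'nearest' is supported")
  structure(
    list(rotation_range = rotation_range, width_shift = width_shift,
         height_shift = height_shift, shear_range = shear_range,
         zoom_range = zoom_range, horizontal_flip = isTRUE(horizontal_flip),
         fill_mode = fill_mode, n_aug_per_frame = as.integer(n_aug_per_frame),
         seed = seed),
    class = "augmentation_config"
  )
}

# apply one random affine (about the image centre) with nearest-neighbour
# sampling and edge replication
random_affine <- function(frame, config) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  theta <- runif(1, -config$rotation_range, config$rotation_range) * pi / 180
  tx <- runif(1, -config$width_shift, config$width_shift) * w
  ty <- runif(1, -config$height_shift, config$height_shift) * h
  sh <- runif(1, -config$shear_range, config$shear_range)
  z <- runif(1, 1 - config$zoom_range, 1 + config$zoom_range)
  flip <- config$horizontal_flip && runif(1) < 0.5

  # forward map (image coords: x = col, y = row):
  # p_out = R(theta) %*% Sh(sh) %*% (z * F) %*% (p - c) + c + t
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shear <- matrix(c(1, 0, sh, 1), 2, 2)
  fl <- diag(c(if (flip) -1 else 1, 1))
  m <- rot %*% shear %*% (z * fl)
  minv <- solve(m)

  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xo <- rep(seq_len(w), each = h) - cx - tx
  yo <- rep(seq_len(h), times = w) - cy - ty
  xs <- minv[1, 1] * xo + minv[1, 2] * yo + cx
  ys <- minv[2, 1] * xo + minv[2, 2] * yo + cy
  ci <- pmin(w, pmax(1L, as.integer(round(xs))))
  ri <- pmin(h, pmax(1L, as.integer(round(ys))))
  idx <- ri + (ci - 1L) * h
  out <- array(0L, dim = dim(frame))
  for (ch in 1:3) out[, , ch] <- frame[, , ch][idx]
  out
}

#' Generate augmented copies of one frame
#'
#' Returns `n_aug_per_frame` randomly transformed copies. With all ranges at
#' zero and flipping off, every copy is pixel-identical to the input. If the
#' config carries a seed, the call is deterministic.
#'
#' @param frame integer array `(h, w, 3)`
#' @param config an [augmentation_config()]
#' @return list of frames
#' @export
augment_frame <- function(frame, config) {
  if (!inherits(config, "augmentation_config"))
    stop_validation("config must be an augmentation_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  lapply(seq_len(config$n_aug_per_frame),
         function(i) random_affine(frame, config))
}

#' Build a labelled image set from video frames
#'
#' Expands each frame of each labelled video into the original plus
#' `n_aug_per_frame` augmented copies, filed under a class-prefixed unique
#' identifier. The result is the tabular corpus consumed by
#' [split_dataset()] and the CNN trainer.
#'
#' @param videos tibble with columns `video` (paths) and `label`
#'   (factor `has_stenosis`/`no_stenosis`), e.g. from [generate_cohort()]
#' @param config an [augmentation_config()]
#' @param seed seed fixed before the (random) augmentation pass
#' @return tibble with columns `filename`, `label`, `video_id`,
#'   `frame_index`, `augmented`, `image` (list column of frames)
#' @export
augment_videos <- function(videos, config = augmentation_config(),
                           seed = 1L) {
  set.seed(seed)
  counter <- 0L
  rows <- list()
  for (v in seq_len(nrow(videos))) {
    seq <- extract_frames(videos$video[v])
    lab <- as.character(videos$label[v])
    for (fi in seq_along(seq$frames)) {
      imgs <- c(list(seq$frames[[fi]]),
                augment_frame(seq$frames[[fi]], config))
      for (k in seq_along(imgs)) {
        counter <- counter + 1L
        rows[[counter]] <- tibble(
          filename = sprintf("%s_%06d", lab, counter),
          label = factor(lab, levels = class_levels()),
          video_id = videos$video[v],
          frame_index = fi,
          augmented = k > 1L,
          image = list(imgs[[k]]))
      }
    }
  }
  bind_rows(rows)
}

#' Split a labelled image set into train / test / holdout
#'
#' First sets aside `holdout_videos` whole videos per class (every frame and
#' augmented copy of a held-out video is excluded from both splits), then
#' splits the remaining images at the image level: a random
#' `test_fraction` of each class goes to the test set, the rest to training.
#' Image-level splitting follows the corpus convention but does allow
#' augmented siblings of one frame to land on both sides; the held-out
#' videos are the leak-free evaluation set.
#'
#' @param images labelled image tibble from [augment_videos()]
#' @param test_fraction proportion of images per class assigned to the test
#'   set (default 0.3)
#' @param holdout_videos whole videos per class excluded from both splits
#' @param seed RNG seed for video selection and the image split
#' @return list with tibbles `train` and `test`, plus `holdout` (character
#'   vector of held-out video ids)
#' @export
split_dataset <- function(images, test_fraction = 0.3, holdout_videos = 2L,
                          seed = 1L) {
  if (test_fraction < 0 || test_fraction > 1)
    stop_validation("test_fraction must lie in [0, 1]")
  present <- unique(as.character(images$label))
  if (!all(class_levels() %in% present))
    stop_validation("both classes must be present in the image set")
  set.seed(seed)

  holdout <- character()
  for (cl in class_levels()) {
    vids <- unique(images$video_id[images$label == cl])
    k <- min(length(vids) - 1L, as.integer(holdout_videos))
    if (k > 0L) holdout <- c(holdout, sample(vids, k))
  }
  pool <- images[!(images$video_id %in% holdout), ]
  if (!all(class_levels() %in% unique(as.character(pool$label))))
    stop_validation("holdout selection removed an entire class")

  test_idx <- integer()
  for (cl in class_levels()) {
    rows <- which(pool$label == cl)
    n_test <- round(test_fraction * length(rows))
    if (n_test > 0L) test_idx <- c(test_idx, sample(rows, n_test))
  }
  list(train = pool[setdiff(seq_len(nrow(pool)), test_idx), ],
       test = pool[test_idx, ],
       holdout = holdout)
}
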