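# broom-style accessors and ggplot2 autoplot methods for the result types

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   facet_wrap labs theme_minimal scale_x_continuous
#' @export
ggplot2::autoplot

#' Tidy the per-threshold records of a threshold scan
#'
#' @param x an `mva_scan`
#' @param ... unused
#' @return tibble with one row per visited threshold: `threshold`,
#'   `best_frame_index`, `area_cm2`, `perimeter_cm`
#' @method tidy mva_scan
#' @export
tidy.mva_scan <- function(x, ...) {
  dplyr::select(x$records, -"contour")
}

#' One-row summary of a threshold scan
#'
#' @param x an `mva_scan`
#' @param ... unused
#' @return tibble with `selected_threshold`, `selected_frame_index`,
#'   `mva_cm2`, `grade`, `stop_reason`, `n_thresholds`
#' @method glance mva_scan
#' @export
glance.mva_scan <- function(x, ...) {
  tibble(
    selected_threshold = x$selected_threshold,
    selected_frame_index = x$selected_frame_index,
    mva_cm2 = x$mva_cm2,
    grade = classify_mva(x$mva_cm2),
    stop_reason = x$stop_reason,
    n_thresholds = nrow(x$records))
}

#' Plot the threshold-scan trace
#'
#' Area and perimeter of the best contour at each visited threshold, with
#' the selected threshold marked.
#'
#' @param object an `mva_scan`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot mva_scan
#' @export
autoplot.mva_scan <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    df, c("area_cm2", "perimeter_cm"),
    names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$threshold, y = .data$value)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$selected_threshold, linetype = "dashed") +
    facet_wrap(~quantity, scales = "free_y",
               labeller = ggplot2::as_labeller(c(
                 area_cm2 = "orifice area (cm²)",
                 perimeter_cm = "contour perimeter (cm)"))) +
    scale_x_continuous(breaks = scales_int_breaks(df$threshold)) +
    labs(x = "gray threshold",
         y = NULL,
         title = sprintf("Threshold scan: MVA %.2f cm² at t = %d (%s)",
                         object$mva_cm2, object$selected_threshold,
                         object$stop_reason)) +
    theme_minimal()
}

scales_int_breaks <- function(x) {
  u <- sort(unique(x))
  if (length(u) > 8) u[seq(1, length(u), by = ceiling(length(u) / 8))] else u
}

#' Tidy the training history of a CNN fit
#'
#' @param x a `cnn_fit`
#' @param ... unused
#' @return the per-epoch history tibble
#' @method tidy cnn_fit
#' @export
tidy.cnn_fit <- function(x, ...) x$history

#' One-row summary of a CNN fit
#'
#' @param x a `cnn_fit`
#' @param ... unused
#' @return tibble with epochs trained, best epoch, and the best epoch's test
#'   loss and accuracy
#' @method glance cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L)
    return(tibble(epochs = 0L, best_epoch = NA_integer_,
                  test_loss = NA_real_, test_accuracy = NA_real_,
                  stopped_early = x$stopped_early))
  tibble(epochs = nrow(h), best_epoch = x$best_epoch,
         test_loss = h$test_loss[x$best_epoch],
         test_accuracy = h$test_accuracy[x$best_epoch],
         stopped_early = x$stopped_early)
}

#' Plot CNN training curves
#'
#' Accuracy and loss per epoch for the training and test sets, in the style
#' of standard training-history panels.
#'
#' @param object a `cnn_fit`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot cnn_fit
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                              values_to = "value")
  long$set <- ifelse(grepl("^train", long$metric), "train", "test")
  long$quantity <- ifelse(grepl("loss$", long$metric), "loss", "accuracy")
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$set)) +
    geom_line() + geom_point() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL,
         title = "CNN training history") +
    theme_minimal()
}

#' Tidy per-frame CNN predictions for a video
#'
#' @param x a `video_prediction`
#' @param ... unused
#' @return tibble of per-frame class probabilities and argmax predictions
#' @method tidy video_prediction
#' @export
tidy.video_prediction <- function(x, ...) x$frame_probs

#' @importFrom rlang .data %||%
NULL
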