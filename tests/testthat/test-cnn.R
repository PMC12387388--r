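# Tiny architectures (same topology, few filters) keep these tests fast;
# the full 32-256 filter stack is exercised by the acceptance experiment.

tiny_spec <- function(...) {
  cnn_spec(input_size = 16L, conv_filters = c(2L, 3L, 4L, 5L),
           dense_units = 6L, batch_size = 4L, ...)
}

# a trivially separable image set: bright class vs dark class
toy_image_set <- function(n_per_class, seed = 1L, size = 16L) {
  set.seed(seed)
  mk <- function(base) {
    array(as.integer(pmin(255, pmax(0, base +
      sample(-20:20, size * size * 3, replace = TRUE)))),
      dim = c(size, size, 3))
  }
  tibble::tibble(
    image = c(lapply(seq_len(n_per_class), function(i) mk(200L)),
              lapply(seq_len(n_per_class), function(i) mk(40L))),
    label = factor(rep(c("has_stenosis", "no_stenosis"), each = n_per_class),
                   levels = c("has_stenosis", "no_stenosis")))
}

test_that("model building validates pooling depth and is reproducible", {
  expect_error(cnn_spec(input_size = 8L),
               class = "echoplanim_validation_error")
  expect_error(cnn_spec(conv_filters = c(32L, 16L)),
               class = "echoplanim_validation_error")
  m1 <- build_model(tiny_spec(), seed = 3L)
  m2 <- build_model(tiny_spec(), seed = 3L)
  expect_identical(lapply(m1$params, dim), lapply(m2$params, dim))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$n_params,
                   sum(vapply(m1$params, length, integer(1))))
})

test_that("the forward pass emits per-image probability distributions", {
  model <- build_model(tiny_spec(), seed = 5L)
  set.seed(6)
  x <- array(runif(16 * 16 * 3 * 7), c(16, 16, 3, 7))
  probs <- echoplanim:::predict_probs(model, x, chunk = 3L)
  expect_identical(dim(probs), c(2L, 7L))
  expect_equal(colSums(probs), rep(1, 7))
  expect_true(all(probs >= 0))
})

test_that("analytic gradients match numerical differentiation", {
  spec <- tiny_spec()
  model <- build_model(spec, seed = 2L)
  set.seed(42)
  n <- 3L
  x <- array(runif(16 * 16 * 3 * n), c(16, 16, 3, n))
  y <- matrix(0, 2, n)
  y[cbind(sample(1:2, n, replace = TRUE), 1:n)] <- 1
  fwd <- echoplanim:::cnn_forward(model$params, spec, x, keep_cache = TRUE)
  grads <- echoplanim:::cnn_backward(model$params, spec, fwd, y)
  loss_at <- function(params)
    echoplanim:::ce_loss(echoplanim:::cnn_forward(params, spec, x)$probs, y)
  eps <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (idx in sample(length(p), min(3, length(p)))) {
      pp <- model$params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm <- model$params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][idx], num, tolerance = 1e-5,
                   info = nm)
    }
  }
})

test_that("training learns a separable toy problem and records history", {
  train <- toy_image_set(12, seed = 7L)
  test <- toy_image_set(6, seed = 8L)
  model <- build_model(tiny_spec(), seed = 9L)
  fit <- cnn_train(model, train, test, epochs = 10, learning_rate = 0.01,
                   seed = 10L)
  h <- fit$history
  expect_true(nrow(h) >= 1)
  expect_named(h, c("epoch", "train_loss", "train_accuracy", "test_loss",
                    "test_accuracy"))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  ev <- cnn_evaluate(fit, test)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(ev$confusion[row(ev$confusion) != col(ev$confusion)] == 0))
  expect_identical(sum(ev$confusion), nrow(test))
})

test_that("zero epochs leaves the model untrained with empty history", {
  train <- toy_image_set(4)
  fit <- cnn_train(build_model(tiny_spec(), seed = 1L), train, train,
                   epochs = 0)
  expect_identical(nrow(fit$history), 0L)
  expect_false(fit$model$trained)
  expect_identical(glance(fit)$epochs, 0L)
})

test_that("a single-class training set is rejected", {
  train <- toy_image_set(4)
  one <- train[train$label == "has_stenosis", ]
  expect_error(cnn_train(build_model(tiny_spec(), seed = 1L), one, train),
               class = "echoplanim_validation_error")
})

test_that("training is reproducible under fixed seeds", {
  train <- toy_image_set(6, seed = 11L)
  test <- toy_image_set(3, seed = 12L)
  f1 <- cnn_train(build_model(tiny_spec(), seed = 2L), train, test,
                  epochs = 2, seed = 5L)
  f2 <- cnn_train(build_model(tiny_spec(), seed = 2L), train, test,
                  epochs = 2, seed = 5L)
  expect_equal(f1$history, f2$history)
  expect_equal(f1$model$params, f2$model$params)
})

test_that("a constant predictor scores 1/2 on a balanced set", {
  model <- build_model(tiny_spec(), seed = 4L)
  # force the head to always say has_stenosis
  model$params$outW[] <- 0
  model$params$outb <- c(5, -5)
  bal <- toy_image_set(5)
  ev <- cnn_evaluate(model, bal)
  expect_equal(ev$accuracy, 0.5)
  expect_identical(sum(ev$confusion), nrow(bal))
})

test_that("predict_video votes over frames and ties go to has_stenosis", {
  model <- build_model(tiny_spec(), seed = 4L)
  model$params$outW[] <- 0
  model$params$outb <- c(5, -5)  # constant has_stenosis
  ph <- render_phantom(small_phantom(1.0, seed = 2, n_frames = 3L))
  path <- withr::local_tempfile(fileext = ".avi")
  write_avi(ph$frames, path)
  pv <- predict_video(model, path)
  expect_identical(as.character(pv$verdict), "has_stenosis")
  expect_equal(pv$frame_probs$p_has_stenosis + pv$frame_probs$p_no_stenosis,
               rep(1, 3))
  expect_identical(nrow(tidy(pv)), 3L)

  # constant no_stenosis head: verdict flips
  model$params$outb <- c(-5, 5)
  expect_identical(as.character(predict_video(model, path)$verdict),
                   "no_stenosis")
})
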