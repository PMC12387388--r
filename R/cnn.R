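# Binary stenosis screening CNN.
#
# Architecture: four conv(3x3, 'same', ReLU) + maxpool(2x2) stages with
# filter counts rising 32 -> 64 -> 128 -> 256, a flatten, a dense ReLU layer
# of 512 units, and a 2-unit softmax head trained with categorical
# cross-entropy under Adam. No deep-learning framework is available in this
# toolchain, so the forward/backward passes run on the package's own
# im2col+GEMM kernels (src/cnn_ops.cpp); the training loop, Adam updates and
# early stopping live here.

#' Specify the screening CNN
#'
#' @param input_size square input resolution in pixels; must survive one
#'   2x2 pooling per conv stage (so at least `2^length(conv_filters)`)
#' @param channels input channels (3 for RGB frames)
#' @param conv_filters filter counts per conv stage, strictly increasing
#' @param kernel odd conv kernel size (3)
#' @param dense_units width of the fully connected layer (512)
#' @param output_units classes in the softmax head (2)
#' @param batch_size minibatch size (100)
#' @param max_epochs training epoch cap (10)
#' @param patience early-stopping patience on test loss (3)
#' @param learning_rate Adam step size (1e-3)
#' @return object of class `cnn_spec`
#' @export
cnn_spec <- function(input_size = 128L, channels = 3L,
                     conv_filters = c(32L, 64L, 128L, 256L), kernel = 3L,
                     dense_units = 512L, output_units = 2L,
                     batch_size = 100L, max_epochs = 10L, patience = 3L,
                     learning_rate = 1e-3) {
  if (length(conv_filters) < 1L || any(diff(conv_filters) <= 0))
    stop_validation("conv_filters must be strictly increasing")
  if (kernel %% 2L != 1L) stop_validation("kernel size must be odd")
  s <- as.integer(input_size)
  for (l in seq_along(conv_filters)) {
    s <- s %/% 2L
    if (s < 1L)
      stop_validation(sprintf(
        "input_size %d is too small for %d pooling stages",
        as.integer(input_size), length(conv_filters)))
  }
  structure(
    list(input_size = as.integer(input_size), channels = as.integer(channels),
         conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
         dense_units = as.integer(dense_units),
         output_units = as.integer(output_units),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         learning_rate = learning_rate),
    class = "cnn_spec"
  )
}

#' Build (initialise) the CNN from its spec
#'
#' He-normal initialisation for all weights, zero biases. Two builds from the
#' same spec and seed are identical; the trainable parameter count is a pure
#' function of the spec and is reported by `print()`.
#'
#' @param spec a [cnn_spec()]
#' @param seed RNG seed for the initial weights
#' @return object of class `cnn_model`
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  k <- spec$kernel
  he <- function(nr, nc, fan_in)
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

  params <- list()
  cin <- spec$channels
  s <- spec$input_size
  for (l in seq_along(spec$conv_filters)) {
    f <- spec$conv_filters[l]
    params[[paste0("convW", l)]] <- he(k * k * cin, f, k * k * cin)
    params[[paste0("convb", l)]] <- numeric(f)
    cin <- f
    s <- s %/% 2L
  }
  flat <- s * s * cin
  params$denseW <- he(flat, spec$dense_units, flat)
  params$denseb <- numeric(spec$dense_units)
  params$outW <- he(spec$dense_units, spec$output_units, spec$dense_units)
  params$outb <- numeric(spec$output_units)

  structure(
    list(spec = spec, params = params,
         n_params = sum(vapply(params, length, integer(1))),
         trained = FALSE),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  sp <- x$spec
  cat(sprintf(
    "<cnn_model: input %dx%dx%d, conv %s (3x3 + maxpool), dense %d, softmax %d>\n",
    sp$input_size, sp$input_size, sp$channels,
    paste(sp$conv_filters, collapse = "-"), sp$dense_units, sp$output_units))
  cat(sprintf("  %s trainable parameters; %s\n",
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# forward pass; returns probs (classes x N) and, optionally, the caches
# needed for backprop
cnn_forward <- function(params, spec, x, keep_cache = FALSE) {
  k <- spec$kernel
  pad <- (k - 1L) %/% 2L
  nl <- length(spec$conv_filters)
  caches <- if (keep_cache) vector("list", nl)
  a <- x
  for (l in seq_len(nl)) {
    z <- cpp_conv_fwd(a, params[[paste0("convW", l)]],
                      params[[paste0("convb", l)]], k, pad)
    r <- z
    r[r < 0] <- 0
    p <- cpp_maxpool_fwd(r, 2L)
    if (keep_cache)
      caches[[l]] <- list(x = a, z = z, argmax = p$argmax, rdim = dim(r))
    a <- p$out
  }
  n <- dim(a)[4]
  flat <- matrix(a, ncol = n)
  zd <- crossprod(params$denseW, flat) + params$denseb
  hd <- zd
  hd[hd < 0] <- 0
  zo <- crossprod(params$outW, hd) + params$outb
  probs <- softmax_cols(zo)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs,
       cache = list(conv = caches, pdim = dim(a), flat = flat,
                    zd = zd, hd = hd))
}

# backward pass for mean cross-entropy; y is a (classes x N) one-hot matrix
cnn_backward <- function(params, spec, fwd, y) {
  k <- spec$kernel
  pad <- (k - 1L) %/% 2L
  n <- ncol(y)
  grads <- list()
  dzo <- (fwd$probs - y) / n
  grads$outW <- fwd$cache$hd %*% t(dzo)
  grads$outb <- rowSums(dzo)
  dhd <- params$outW %*% dzo
  dzd <- dhd * (fwd$cache$zd > 0)
  grads$denseW <- fwd$cache$flat %*% t(dzd)
  grads$denseb <- rowSums(dzd)
  dflat <- params$denseW %*% dzd
  da <- array(dflat, dim = fwd$cache$pdim)
  for (l in rev(seq_along(spec$conv_filters))) {
    cc <- fwd$cache$conv[[l]]
    dr <- cpp_maxpool_bwd(cc$argmax, da, cc$rdim)
    dz <- dr * (cc$z > 0)
    bw <- cpp_conv_bwd(cc$x, params[[paste0("convW", l)]], dz, k, pad)
    grads[[paste0("convW", l)]] <- bw$dW
    grads[[paste0("convb", l)]] <- as.numeric(bw$db)
    da <- bw$dx
  }
  grads[names(params)]
}

ce_loss <- function(probs, y) {
  -mean(log(pmax(colSums(probs * y), 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Stack a labelled image set into model tensors
#'
#' Resizes every image to the model input resolution (nearest neighbour),
#' scales intensities to `[0, 1]`, and one-hot encodes the labels.
#'
#' @param images labelled image tibble (columns `image`, `label`)
#' @param spec a [cnn_spec()]
#' @return list with `x` (array `input_size x input_size x channels x N`) and
#'   `y` (one-hot matrix `classes x N`)
#' @export
image_set_to_tensor <- function(images, spec) {
  n <- nrow(images)
  if (n == 0L) stop_validation("image set is empty")
  s <- spec$input_size
  x <- array(0, dim = c(s, s, spec$channels, n))
  for (i in seq_len(n))
    x[, , , i] <- resize_frame(images$image[[i]], s, s) / 255
  lab <- factor(as.character(images$label), levels = class_levels())
  y <- matrix(0, nrow = length(class_levels()), ncol = n,
              dimnames = list(class_levels(), NULL))
  y[cbind(as.integer(lab), seq_len(n))] <- 1
  list(x = x, y = y)
}

predict_probs <- function(model, x, chunk = 200L) {
  n <- dim(x)[4]
  probs <- matrix(0, nrow = model$spec$output_units, ncol = n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    probs[, i:j] <- cnn_forward(model$params, model$spec,
                                x[, , , i:j, drop = FALSE])$probs
    i <- j + 1L
  }
  rownames(probs) <- class_levels()
  probs
}

#' Train the screening CNN
#'
#' Minibatch Adam on categorical cross-entropy, up to `max_epochs` epochs,
#' monitoring the test (validation) loss after every epoch. Training halts
#' early when the test loss has not improved for `patience` consecutive
#' epochs, and the weights from the best epoch are restored.
#'
#' @param model a [build_model()] result
#' @param train,test labelled image tibbles (columns `image`, `label`); both
#'   classes must be present in the training set
#' @param epochs,batch_size,patience,learning_rate override the spec values
#' @param seed RNG seed for minibatch shuffling
#' @param verbose print one line per epoch
#' @return object of class `cnn_fit`: the trained `model`, a per-epoch
#'   `history` tibble, `best_epoch` and `stopped_early`
#' @export
cnn_train <- function(model, train, test, epochs = NULL, batch_size = NULL,
                      patience = NULL, learning_rate = NULL, seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  spec <- model$spec
  epochs <- if (is.null(epochs)) spec$max_epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) spec$batch_size else as.integer(batch_size)
  patience <- if (is.null(patience)) spec$patience else as.integer(patience)
  lr <- if (is.null(learning_rate)) spec$learning_rate else learning_rate

  if (length(unique(as.character(train$label))) < 2L)
    stop_validation("training set must contain both classes")

  tr <- image_set_to_tensor(train, spec)
  te <- image_set_to_tensor(test, spec)
  n <- dim(tr$x)[4]

  history <- list()
  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  stalled <- 0L
  stopped_early <- FALSE
  set.seed(seed)

  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    tot_loss <- 0
    tot_correct <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(n, i + batch_size - 1L)
      bi <- idx[i:j]
      xb <- tr$x[, , , bi, drop = FALSE]
      yb <- tr$y[, bi, drop = FALSE]
      fwd <- cnn_forward(params, spec, xb, keep_cache = TRUE)
      tot_loss <- tot_loss + ce_loss(fwd$probs, yb) * length(bi)
      tot_correct <- tot_correct +
        sum(apply(fwd$probs, 2, which.max) == apply(yb, 2, which.max))
      grads <- cnn_backward(params, spec, fwd, yb)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      i <- j + 1L
    }
    model$params <- params
    test_probs <- predict_probs(model, te$x)
    test_loss <- ce_loss(test_probs, te$y)
    test_acc <- mean(apply(test_probs, 2, which.max) ==
                       apply(te$y, 2, which.max))
    history[[ep]] <- tibble(
      epoch = ep, train_loss = tot_loss / n, train_accuracy = tot_correct / n,
      test_loss = test_loss, test_accuracy = test_acc)
    if (verbose)
      message(sprintf(
        "epoch %d: train loss %.4f acc %.3f | test loss %.4f acc %.3f",
        ep, tot_loss / n, tot_correct / n, test_loss, test_acc))
    if (test_loss < best$loss) {
      best <- list(loss = test_loss, params = params, epoch = ep)
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= patience) {
        stopped_early <- TRUE
        break
      }
    }
  }

  model$params <- best$params
  model$trained <- length(history) > 0L
  structure(
    list(model = model,
         history = if (length(history)) bind_rows(history) else
           tibble(epoch = integer(), train_loss = numeric(),
                  train_accuracy = numeric(), test_loss = numeric(),
                  test_accuracy = numeric()),
         best_epoch = best$epoch,
         stopped_early = stopped_early),
    class = "cnn_fit"
  )
}

#' @export
print.cnn_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    cat("<cnn_fit: untrained (0 epochs)>\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<cnn_fit: %d epoch(s)%s, best epoch %d (test loss %.4f, test accuracy %.3f)>\n",
    nrow(h), if (x$stopped_early) ", stopped early" else "",
    x$best_epoch, h$test_loss[x$best_epoch], h$test_accuracy[x$best_epoch]))
  invisible(x)
}

#' Evaluate the CNN on a labelled image set
#'
#' @param model a `cnn_model` or `cnn_fit`
#' @param images labelled image tibble
#' @return object of class `cnn_eval`: `accuracy`, `loss`, and `confusion`,
#'   a 2x2 matrix (rows = truth, cols = prediction) with `has_stenosis` as
#'   the positive class
#' @export
cnn_evaluate <- function(model, images) {
  if (inherits(model, "cnn_fit")) model <- model$model
  if (nrow(images) == 0L) stop_validation("evaluation set is empty")
  te <- image_set_to_tensor(images, model$spec)
  probs <- predict_probs(model, te$x)
  truth <- factor(class_levels()[apply(te$y, 2, which.max)],
                  levels = class_levels())
  pred <- factor(class_levels()[apply(probs, 2, which.max)],
                 levels = class_levels())
  structure(
    list(accuracy = mean(pred == truth),
         loss = ce_loss(probs, te$y),
         confusion = table(truth = truth, predicted = pred)),
    class = "cnn_eval"
  )
}

#' @export
print.cnn_eval <- function(x, ...) {
  cat(sprintf("<cnn_eval: accuracy %.3f, loss %.4f>\n", x$accuracy, x$loss))
  print(x$confusion)
  invisible(x)
}

#' Classify a video frame by frame
#'
#' Every frame is resized to the model input, normalised to `[0, 1]` and
#' passed through the network; the video-level verdict is the majority vote
#' over frame argmaxes, with ties resolved to `has_stenosis` (the clinically
#' conservative call). Raw per-frame probabilities are returned for further
#' analysis.
#'
#' @param model a trained `cnn_model` or `cnn_fit`
#' @param video_path path to an AVI video
#' @return object of class `video_prediction`: `frame_probs` (tibble with
#'   per-frame class probabilities and argmax) and `verdict`
#' @export
predict_video <- function(model, video_path) {
  if (inherits(model, "cnn_fit")) model <- model$model
  seq <- extract_frames(video_path)
  s <- model$spec$input_size
  n <- length(seq$frames)
  x <- array(0, dim = c(s, s, model$spec$channels, n))
  for (i in seq_len(n)) x[, , , i] <- resize_frame(seq$frames[[i]], s, s) / 255
  probs <- predict_probs(model, x)
  pred <- factor(class_levels()[apply(probs, 2, which.max)],
                 levels = class_levels())
  votes_has <- sum(pred == "has_stenosis")
  verdict <- if (votes_has >= n / 2) "has_stenosis" else "no_stenosis"
  structure(
    list(frame_probs = tibble(
           frame = seq_len(n),
           p_has_stenosis = probs["has_stenosis", ],
           p_no_stenosis = probs["no_stenosis", ],
           prediction = pred),
         verdict = factor(verdict, levels = class_levels()),
         video = video_path),
    class = "video_prediction"
  )
}

#' @export
print.video_prediction <- function(x, ...) {
  cat(sprintf("<video_prediction: %s (%d/%d frames voted has_stenosis)>\n",
              as.character(x$verdict),
              sum(x$frame_probs$prediction == "has_stenosis"),
              nrow(x$frame_probs)))
  invisible(x)
}
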