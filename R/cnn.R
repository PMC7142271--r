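#' CNN configuration
#'
#' Defaults follow the reference architecture for connectivity images: two
#' stacked 3x3 convolutions (32 filters each, stride 1, one-pixel padding),
#' one 2x2/stride-2 max pooling, a 512-unit fully connected ReLU layer with
#' dropout 0.5, and a two-way softmax. Training uses Adam (learning rate
#' 1e-3, moment decays 0.9/0.999), Xavier initialization, 15 epochs with
#' batch size 30, and keep-best-epoch early stopping on validation
#' accuracy.
#'
#' @param in_channels 1 (single band) or 3 (RGB band stack).
#' @param conv_filters Filters per convolutional layer.
#' @param fc_hidden Fully connected hidden units.
#' @param n_classes Output classes.
#' @param dropout_p Dropout probability on the FC hidden layer.
#' @param lr,adam_beta1,adam_beta2 Adam hyperparameters.
#' @param epochs,batch Training epochs and batch size.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `cnn_config`.
#' @export
cnn_config <- function(in_channels = 1, conv_filters = 32, fc_hidden = 512,
                       n_classes = 2, dropout_p = 0.5, lr = 1e-3,
                       adam_beta1 = 0.9, adam_beta2 = 0.999, epochs = 15,
                       batch = 30, seed = 1) {
  stopifnot(in_channels %in% c(1, 3), conv_filters >= 1, fc_hidden >= 1,
            n_classes >= 2, dropout_p >= 0, dropout_p < 1, lr >= 0,
            epochs >= 1, batch >= 1)
  structure(list(in_channels = in_channels, conv_filters = conv_filters,
                 kernel = 3, stride = 1, pad = 1, n_conv = 2, pool = 2,
                 fc_hidden = fc_hidden, n_classes = n_classes,
                 dropout_p = dropout_p, lr = lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, epochs = epochs, batch = batch,
                 init = "xavier", seed = seed),
            class = "cnn_config")
}

xavier <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Build an untrained CNN for a given image side
#'
#' Layer sequence: conv(3x3, pad 1) -> ReLU -> conv -> ReLU -> maxpool
#' 2x2/2 -> FC(`fc_hidden`) -> ReLU -> dropout -> FC(`n_classes`) ->
#' softmax. The input side must be even (the single pooling stage halves
#' it); a 90 x 90 input yields a pooled feature map of 45 x 45 x
#' `conv_filters`. Weights are Xavier-initialized deterministically from
#' `cfg$seed`.
#'
#' @param cfg A [cnn_config()].
#' @param input_side Image side in pixels.
#' @return A `cnn_model` (untrained).
#' @export
build_cnn <- function(cfg, input_side) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (input_side %% 2 != 0) {
    stop("input side ", input_side, " is not even: 2x2/2 pooling needs an ",
         "even side (pad or crop the image)", call. = FALSE)
  }
  k <- cfg$conv_filters
  cin <- cfg$in_channels
  D <- (input_side / 2)^2 * k
  weights <- with_seed(cfg$seed, list(
    W1 = array(xavier(9 * cin, 9 * k, 9 * cin * k), dim = c(3, 3, cin, k)),
    b1 = numeric(k),
    W2 = array(xavier(9 * k, 9 * k, 9 * k * k), dim = c(3, 3, k, k)),
    b2 = numeric(k),
    W3 = matrix(xavier(D, cfg$fc_hidden, D * cfg$fc_hidden), D, cfg$fc_hidden),
    b3 = numeric(cfg$fc_hidden),
    W4 = matrix(xavier(cfg$fc_hidden, cfg$n_classes,
                       cfg$fc_hidden * cfg$n_classes),
                cfg$fc_hidden, cfg$n_classes),
    b4 = numeric(cfg$n_classes)))
  structure(list(cfg = cfg, input_side = input_side, weights = weights,
                 flat_dim = D, history = NULL, best_epoch = NA_integer_,
                 classes = NULL, trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> %dx%dx%d input, conv %d filters x2, pooled dim %d, FC %d -> %d%s\n",
    x$input_side, x$input_side, x$cfg$in_channels, x$cfg$conv_filters,
    x$flat_dim, x$cfg$fc_hidden, x$cfg$n_classes,
    if (x$trained) sprintf(" [trained, best epoch %d]", x$best_epoch)
    else " [untrained]"))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `cnn_model`.
#' @return Named integer vector of per-tensor counts plus `total`.
#' @export
n_parameters <- function(model) {
  n <- vapply(model$weights, length, 0L)
  c(n, total = sum(n))
}

#' Numerically stable softmax
#'
#' Shift-invariant and safe for large inputs (log-sum-exp stabilization).
#' Components are positive and sum to one.
#'
#' @param v Finite numeric vector.
#' @return Probability vector of the same length.
#' @export
softmax <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  e <- exp(v - max(v))
  e / sum(e)
}

# Internal: stack a list of fc_images into an (side, side, C, N) array.
images_to_array <- function(imgs) {
  d <- dim(imgs[[1]])
  side <- d[1]
  nch <- if (length(d) == 3) d[3] else 1
  out <- array(0, dim = c(side, side, nch, length(imgs)))
  for (k in seq_along(imgs)) out[, , , k] <- unclass(imgs[[k]])
  out
}

check_x <- function(model, x) {
  if (is.list(x)) x <- images_to_array(x)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  if (d[1] != model$input_side || d[2] != model$input_side ||
      d[3] != model$cfg$in_channels) {
    stop(sprintf("input is %d x %d x %d but the model expects %d x %d x %d",
                 d[1], d[2], d[3], model$input_side, model$input_side,
                 model$cfg$in_channels), call. = FALSE)
  }
  x
}

forward_batched <- function(model, x, chunk = 128) {
  n <- dim(x)[4]
  probs <- matrix(0, n, model$cfg$n_classes)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1)
    xb <- x[, , , idx, drop = FALSE]
    res <- cnn_batch_cpp(xb, dim(xb), model$weights, integer(0),
                         matrix(0, 0, 0), FALSE)
    probs[idx, ] <- res$prob
  }
  probs
}

#' Train the CNN
#'
#' Mini-batch Adam on the cross-entropy loss for `cfg$epochs` epochs.
#' Validation accuracy is measured after every epoch and the weights of the
#' best epoch are kept (early stopping inside a fixed epoch budget). With no
#' validation set, early stopping is disabled with a warning and the final
#' weights are returned. Deterministic for a fixed `cfg$seed` and data
#' order.
#'
#' @param model An untrained (or trained) `cnn_model`.
#' @param x_train Array side x side x channels x n (or list of `fc_image`).
#' @param y_train Labels: factor, character or 0/1 vector.
#' @param x_val,y_val Optional validation set (disjoint subjects from
#'   training).
#' @return A trained `cnn_model` with a `history` tibble and `best_epoch`.
#' @export
train_cnn <- function(model, x_train, y_train, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$cfg
  x_train <- check_x(model, x_train)
  yt <- encode_labels(y_train, model$classes)
  model$classes <- yt$classes
  n <- dim(x_train)[4]
  stopifnot(length(yt$y) == n)
  has_val <- !is.null(x_val)
  if (has_val) {
    x_val <- check_x(model, x_val)
    yv <- encode_labels(y_val, model$classes)$y
  } else {
    warning("no validation set: early stopping disabled, final weights kept")
  }
  res <- with_seed(cfg$seed, {
    order <- t(vapply(seq_len(cfg$epochs), function(e) sample.int(n),
                      integer(n)))
    if (!is.matrix(order)) order <- matrix(order, nrow = cfg$epochs)
    cnn_train_cpp(
      x_train, dim(x_train), yt$y, model$weights,
      if (has_val) x_val else numeric(0),
      if (has_val) dim(x_val) else integer(0),
      if (has_val) yv else integer(0),
      order, cfg$lr, cfg$adam_beta1, cfg$adam_beta2, cfg$dropout_p,
      cfg$batch)
  })
  model$weights <- res$weights
  model$best_epoch <- res$best_epoch
  model$history <- tibble::tibble(
    epoch = seq_len(cfg$epochs), train_loss = res$train_loss,
    train_acc = res$train_acc, val_acc = res$val_acc)
  model$trained <- TRUE
  model
}

encode_labels <- function(y, classes = NULL) {
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(list(y = as.integer(y), classes = classes %||% c("0", "1")))
  }
  classes <- classes %||% sort(unique(y))
  idx <- match(y, classes) - 1L
  if (anyNA(idx)) stop("unknown label(s): ",
                       paste(setdiff(y, classes), collapse = ", "),
                       call. = FALSE)
  list(y = idx, classes = classes)
}

#' @export
#' @param object A `cnn_model`.
#' @param newdata Image array or list of `fc_image`.
#' @param type `"prob"` for class probabilities, `"class"` for labels.
#' @param ... Unused.
#' @rdname train_cnn
predict.cnn_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  x <- check_x(object, newdata)
  p <- forward_batched(object, x)
  colnames(p) <- object$classes %||% as.character(seq_len(ncol(p)) - 1)
  if (type == "prob") return(p)
  cls <- colnames(p)[max.col(p, ties.method = "first")]
  cls
}

#' ROC curve and area under it
#'
#' Operating points from the positive-class score, with ties grouped; AUC by
#' the trapezoid rule.
#'
#' @param scores Positive-class probabilities/scores.
#' @param labels True labels (0/1, logical, or factor with the positive
#'   class last).
#' @param positive Positive class (defaults to the larger label).
#' @return List with `points` (tibble `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    positive <- positive %||% sort(unique(labels))[length(unique(labels))]
    y <- as.integer(labels == positive)
  } else {
    y <- as.integer(labels != 0)
  }
  np <- sum(y == 1)
  nn <- sum(y == 0)
  if (np == 0 || nn == 0) {
    stop("ROC undefined: test set contains a single class", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  uniq <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(yy)[uniq]
  fp <- cumsum(1 - yy)[uniq]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = tibble::tibble(fpr = fpr, tpr = tpr,
                               threshold = c(Inf, s[uniq])),
       auc = auc)
}

#' Evaluate a trained model on a test set
#'
#' @param model Trained `cnn_model`.
#' @param x Test images.
#' @param y Test labels.
#' @return List with `accuracy`, `roc` (tibble of operating points), `auc`
#'   and the probability matrix.
#' @export
evaluate_cnn <- function(model, x, y) {
  stopifnot(isTRUE(model$trained))
  p <- predict(model, x, type = "prob")
  enc <- encode_labels(y, model$classes)
  acc <- mean(max.col(p, ties.method = "first") - 1L == enc$y)
  roc <- roc_curve(p[, 2], enc$y)
  list(accuracy = acc, roc = roc$points, auc = roc$auc, prob = p)
}

#' @export
tidy.cnn_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = numeric(),
                          train_acc = numeric(), val_acc = numeric()))
  }
  x$history
}

#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = unname(n_parameters(x)["total"]),
    input_side = x$input_side,
    in_channels = x$cfg$in_channels,
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_acc = if (is.null(x$history)) NA_real_ else
      suppressWarnings(max(x$history$val_acc, na.rm = TRUE)))
}
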