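test_that("softmax is a stable probability simplex map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(1), log(3))), c(0.25, 0.75))
  big <- softmax(c(1000, 0))
  expect_equal(big[1], 1, tolerance = 1e-9)
  expect_false(any(is.nan(big)))
  set.seed(1)
  for (k in 1:20) {
    p <- softmax(rnorm(sample(2:6, 1), sd = 10))
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
  }
  # shift invariance
  v <- rnorm(4)
  expect_equal(softmax(v), softmax(v + 57.3), tolerance = 1e-12)
})

test_that("model geometry matches the architecture arithmetic", {
  m <- build_cnn(cnn_config(in_channels = 1), 90)
  expect_equal(m$flat_dim, 45 * 45 * 32)
  expect_equal(m$flat_dim, 64800)
  m3 <- build_cnn(cnn_config(in_channels = 3), 90)
  # first conv layer parameter count: (3*3*3 + 1) * 32
  expect_equal(length(m3$weights$W1) + length(m3$weights$b1), 896)
  expect_equal(dim(m3$weights$W1), c(3, 3, 3, 32))
  expect_equal(dim(m$weights$W3), c(64800, 512))
  expect_equal(dim(m$weights$W4), c(512, 2))
  expect_error(build_cnn(cnn_config(), 91), "even")
  # identical seeds give identical initial weights
  a <- build_cnn(cnn_config(seed = 5), 22)
  b <- build_cnn(cnn_config(seed = 5), 22)
  expect_identical(a$weights, b$weights)
  expect_false(identical(build_cnn(cnn_config(seed = 6), 22)$weights,
                         a$weights))
})

test_that("forward pass matches a double-precision reference implementation", {
  set.seed(2)
  cfg <- cnn_config(in_channels = 3, conv_filters = 3, fc_hidden = 5,
                    dropout_p = 0, seed = 42)
  m <- build_cnn(cfg, 6)
  m$weights <- offset_weights(m$weights)
  x <- array(rnorm(6 * 6 * 3 * 3), dim = c(6, 6, 3, 3))
  got <- fcnet:::cnn_batch_cpp(x, dim(x), m$weights, integer(0),
                               matrix(0, 0, 0), FALSE)$prob
  for (n in 1:3) {
    want <- ref_forward(m$weights, array(x[, , , n], dim = c(6, 6, 3)))
    expect_equal(got[n, ], as.vector(want), tolerance = 1e-5)
  }
})

test_that("analytic gradients match numeric differentiation of the reference", {
  set.seed(3)
  cfg <- cnn_config(in_channels = 1, conv_filters = 3, fc_hidden = 7,
                    dropout_p = 0, seed = 42)
  m <- build_cnn(cfg, 6)
  m$weights <- offset_weights(m$weights)
  x <- array(rnorm(6 * 6 * 1 * 4), dim = c(6, 6, 1, 4))
  y <- c(0L, 1L, 1L, 0L)
  res <- fcnet:::cnn_batch_cpp(x, dim(x), m$weights, y, matrix(0, 0, 0), TRUE)
  expect_equal(res$loss, ref_loss(m$weights, x, y), tolerance = 1e-5)
  for (nm in names(m$weights)) {
    d <- array(rnorm(length(m$weights[[nm]])),
               dim = if (is.null(dim(m$weights[[nm]])))
                 length(m$weights[[nm]]) else dim(m$weights[[nm]]))
    eps <- 1e-5
    wp <- m$weights; wp[[nm]] <- wp[[nm]] + eps * d
    wm <- m$weights; wm[[nm]] <- wm[[nm]] - eps * d
    numd <- (ref_loss(wp, x, y) - ref_loss(wm, x, y)) / (2 * eps)
    ana <- sum(res$grads[[nm]] * d)
    expect_equal(ana, numd, tolerance = 1e-4)
  }
})

test_that("training overfits a tiny set and the loss decreases early", {
  set.seed(4)
  cfg <- cnn_config(in_channels = 1, seed = 9)
  x <- array(runif(22 * 22 * 10), dim = c(22, 22, 1, 10))
  y <- rep(c(0, 1), 5)
  m <- suppressWarnings(train_cnn(build_cnn(cfg, 22), x, y))
  h <- tidy(m)
  expect_equal(h$train_acc[nrow(h)], 1)
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_equal(m$best_epoch, cfg$epochs)  # no validation set
})

test_that("zero learning rate leaves weights untouched", {
  cfg <- cnn_config(in_channels = 1, conv_filters = 2, fc_hidden = 4,
                    lr = 0, dropout_p = 0, epochs = 2, seed = 3)
  m0 <- build_cnn(cfg, 8)
  w_init <- lapply(m0$weights, function(p) p + 0)
  x <- array(runif(8 * 8 * 6), dim = c(8, 8, 1, 6))
  m1 <- suppressWarnings(train_cnn(m0, x, rep(c(0, 1), 3)))
  expect_equal(m1$weights, w_init, tolerance = 1e-6)
  expect_lt(diff(range(tidy(m1)$train_loss)), 1e-6)
  # and the original model object was not mutated
  expect_equal(m0$weights, w_init, tolerance = 1e-12)
})

test_that("training is deterministic and early stopping keeps the best epoch", {
  set.seed(6)
  cfg <- cnn_config(in_channels = 1, conv_filters = 4, fc_hidden = 8,
                    epochs = 5, seed = 31)
  x <- array(runif(10 * 10 * 40), dim = c(10, 10, 1, 40))
  y <- rep(c(0, 1), 20)
  x[1:3, 1:3, 1, y == 1] <- x[1:3, 1:3, 1, y == 1] + 0.5
  xv <- x[, , , 1:10, drop = FALSE]
  a <- train_cnn(build_cnn(cfg, 10), x, y, xv, y[1:10])
  b <- train_cnn(build_cnn(cfg, 10), x, y, xv, y[1:10])
  expect_identical(a$weights, b$weights)
  expect_identical(tidy(a), tidy(b))
  expect_equal(a$best_epoch, which.max(tidy(a)$val_acc))
  g <- glance(a)
  expect_equal(g$best_val_acc, max(tidy(a)$val_acc))
  expect_gt(g$n_parameters, 0)
})

test_that("shuffled labels keep validation accuracy at chance", {
  set.seed(7)
  accs <- sapply(1:5, function(s) {
    cfg <- cnn_config(in_channels = 1, conv_filters = 4, fc_hidden = 8,
                      epochs = 6, seed = 200 + s)
    x <- array(runif(10 * 10 * 60), dim = c(10, 10, 1, 60))
    y <- sample(rep(c(0, 1), 30))
    m <- train_cnn(build_cnn(cfg, 10), x[, , , 1:40, drop = FALSE], y[1:40],
                   x[, , , 41:60, drop = FALSE], y[41:60])
    tail(tidy(m)$val_acc, 1)  # final epoch, unbiased by best-epoch selection
  })
  # 5 seeds x 20 validation trials: 99% binomial bounds around 0.5
  half_width <- qnorm(0.995) * sqrt(0.25 / (5 * 20))
  expect_lt(abs(mean(accs) - 0.5), half_width + 0.05)
})

test_that("evaluation produces accuracy, ROC and AUC with sane behavior", {
  # perfectly separable toy set
  set.seed(8)
  cfg <- cnn_config(in_channels = 1, conv_filters = 4, fc_hidden = 8,
                    dropout_p = 0, epochs = 20, batch = 10, seed = 5)
  x <- array(runif(10 * 10 * 30), dim = c(10, 10, 1, 30))
  y <- rep(c(0, 1), 15)
  x[, , 1, y == 1] <- x[, , 1, y == 1] + 1
  m <- suppressWarnings(train_cnn(build_cnn(cfg, 10), x, y))
  ev <- evaluate_cnn(m, x, y)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_error(evaluate_cnn(m, x[, , , y == 1, drop = FALSE], y[y == 1]),
               "single class")

  # random scores give AUC near 1/2; cross-check the trapezoid against pROC
  set.seed(9)
  sc <- runif(1000)
  lb <- rep(c(0, 1), 500)
  rc <- roc_curve(sc, lb)
  expect_lt(abs(rc$auc - 0.5), 0.05)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, sc))))
    expect_equal(rc$auc, ref, tolerance = 1e-9)
  }

  # a constant classifier on a balanced set is 50% accurate
  m0 <- m
  m0$weights$W4[] <- 0
  m0$weights$b4 <- c(5, 0)  # always class 1
  p <- predict(m0, x, type = "prob")
  expect_true(all(p[, 1] > 0.99))
  acc <- mean(max.col(p, ties.method = "first") - 1L == y)
  expect_equal(acc, 0.5)
})
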