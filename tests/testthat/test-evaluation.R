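test_that("subject-wise folds partition the cohort with the stated sizes", {
  ids <- c(sprintf("case%02d", 1:24), sprintf("ctrl%02d", 1:24))
  grp <- rep(c("case", "control"), each = 24)
  folds <- make_subjectwise_folds(ids, grp, 24)
  expect_equal(nrow(folds), 24)
  for (i in 1:24) {
    expect_length(folds$test[[i]], 2)
    expect_length(folds$validation[[i]], 2)
    expect_length(folds$train[[i]], 44)
    expect_length(unique(c(folds$test[[i]], folds$validation[[i]],
                           folds$train[[i]])), 48)
  }
  # test sets tile the cohort exactly once
  all_test <- unlist(folds$test)
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  # one subject of each group per test pair
  expect_true(all(vapply(folds$test, function(s) {
    length(unique(grp[match(s, ids)])) == 2
  }, TRUE)))
})

test_that("fold arithmetic scales down and rejects unbalanced cohorts", {
  folds <- make_subjectwise_folds(paste0("s", 1:6),
                                  rep(c("a", "b"), each = 3), 3)
  expect_true(all(vapply(folds$train, length, 0L) == 2))
  expect_error(make_subjectwise_folds(paste0("s", 1:5),
                                      c("a", "a", "a", "b", "b"), 3),
               "at least n_folds")
  expect_error(make_subjectwise_folds(c("s1", "s1"), c("a", "b")),
               "duplicate")
})

toy_image_data <- function(n_per_group, side = 8, effect = 0, seed = 1,
                           trials = 4) {
  set.seed(seed)
  rows <- list()
  for (g in c("control", "case")) {
    for (s in seq_len(n_per_group)) {
      id <- paste0(substr(g, 1, 2), s)
      for (tr in seq_len(trials)) {
        img <- matrix(runif(side * side), side, side)
        if (g == "case") img <- img + effect
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = id, group = g, trial = tr,
          image = list(structure(img, class = c("fc_image", "matrix"))))
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("run_cv separates groups with signal and is deterministic", {
  dat <- toy_image_data(3, side = 8, effect = 0.8, seed = 2)
  # small batches + raised learning rate so the tiny 8-image training sets
  # get enough optimizer steps to learn the offset
  cfg <- cnn_config(in_channels = 1, conv_filters = 4, fc_hidden = 8,
                    epochs = 40, batch = 4, dropout_p = 0, lr = 5e-3)
  cv <- run_cv(dat, cfg, n_folds = 3, repeats = 2, seed = 5)
  expect_s3_class(cv, "cv_result")
  expect_gt(cv$mean_accuracy, 0.9)
  expect_equal(nrow(cv$per_fold), 6)
  expect_equal(sum(cv$per_fold$n_test), 2 * 2 * 4 * 3 / 3 * 3)
  cv2 <- run_cv(dat, cfg, n_folds = 3, repeats = 2, seed = 5)
  expect_identical(glance(cv), glance(cv2))
  expect_identical(tidy(cv), tidy(cv2))
  g <- glance(cv)
  expect_true(all(c("mean_accuracy", "sd_accuracy", "mean_auc") %in%
                    names(g)))
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("mean connectivity features follow the direct formula", {
  cm <- fc_matrix(matrix(0.3, 5, 5), "coherence")
  toy <- matrix(c(1, 0.1, 0.2,
                  0.1, 1, 0.4,
                  0.2, 0.4, 1), 3, 3)
  tm <- fc_matrix(toy, "plv")
  tbl <- tibble::tibble(subject_id = "s1", group = "case", trial = 1:2,
                        block = "Neu", metric = "plv", band = "alpha",
                        matrix = list(cm, tm))
  feats <- mean_fc_features(tbl)
  expect_equal(nrow(feats), 2)
  expect_equal(feats$feature[1], 0.3)
  expect_equal(feats$feature[2], mean(c(0.1, 0.2, 0.4)))
  expect_false("matrix" %in% names(feats))
})

test_that("baseline classifiers ace separable features and stay near chance on noise", {
  mk_features <- function(effect, seed) {
    set.seed(seed)
    n_per <- 4; trials <- 8
    rows <- list()
    for (g in c("control", "case")) {
      for (s in seq_len(n_per)) {
        mu <- if (g == "case") effect else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = paste0(substr(g, 1, 2), s), group = g,
          trial = seq_len(trials), feature = rnorm(trials, mu, 0.2))
      }
    }
    dplyr::bind_rows(rows)
  }
  sep <- mk_features(5, 1)
  folds <- make_subjectwise_folds(unique(sep$subject_id),
                                  rep(c("control", "case"), each = 4), 4)
  acc <- baseline_classifiers(sep, folds, seed = 2)
  expect_equal(max(acc$accuracy), 1)
  expect_setequal(acc$classifier,
                  c("naive_bayes", "logistic", "knn_1", "knn_5", "knn_10",
                    "random_forest"))

  null <- mk_features(0, 3)
  acc0 <- baseline_classifiers(null, folds, seed = 2)
  # 64 test trials; chance plus selection inflation over 6 classifiers
  bound <- 0.5 + qnorm(1 - 0.01 / 6) * sqrt(0.25 / 64)
  expect_lt(max(acc0$accuracy), bound + 0.05)

  acc0b <- baseline_classifiers(null, folds, seed = 2)
  expect_identical(acc0, acc0b)

  const <- null
  const$feature <- 1
  expect_warning(baseline_classifiers(const, folds), "constant")
})

test_that("with zero group effect downstream CV accuracy is at chance", {
  # generator null calibration: 5 independent cohorts, feature baselines
  accs <- sapply(1:5, function(k) {
    sp <- cohort_spec(n_per_group = 4, n_epochs = 6, epoch_len_s = 2,
                      fs = 250, n_channels = 6,
                      base = coupling_spec("alpha", noise_sd = 0.5),
                      seed = 900 + k)
    tbl <- cohort_connectivity(generate_cohort(sp), "plv", "alpha",
                               trim_s = 0.25)
    feats <- mean_fc_features(tbl)
    folds <- make_subjectwise_folds(unique(feats$subject_id),
                                    rep(c("control", "case"), each = 4), 4)
    max(baseline_classifiers(feats, folds, seed = k)$accuracy)
  })
  # max over 6 classifiers inflates the null; bound by mean accuracy over
  # cohorts against binomial noise at the subject level (8 subjects x 5)
  expect_lt(mean(accs), 0.5 + qnorm(0.995) * sqrt(0.25 / 40) + 0.1)
})

test_that("reports summarize conditions and warn when empty", {
  dat <- toy_image_data(3, side = 6, effect = 0.5, seed = 4, trials = 2)
  cfg <- cnn_config(in_channels = 1, conv_filters = 2, fc_hidden = 4,
                    epochs = 2)
  cv <- run_cv(dat, cfg, n_folds = 3, repeats = 1, seed = 1)
  tab <- report_cv(list("plv/alpha/Neu" = cv, "plv/alpha/Emo" = cv))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$condition[1], "plv/alpha/Neu")
  expect_warning(empty <- report_cv(list()), "no CV results")
  expect_equal(nrow(empty), 0)
})
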