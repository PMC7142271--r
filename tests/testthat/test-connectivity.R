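test_that("identical channels give the metric self-values", {
  set.seed(1)
  x <- rnorm(1500)
  rec <- rec_from_signals(cbind(x, x, rnorm(1500)))
  expect_equal(coherence_matrix(rec, "alpha")[[1]][1, 2], 1, tolerance = 1e-9)
  expect_equal(correlation_matrix(rec, "alpha")[[1]][1, 2], 1,
               tolerance = 1e-9)
  expect_equal(plv_matrix(rec, "alpha")[[1]][1, 2], 1, tolerance = 1e-9)
  expect_equal(pli_matrix(rec, "alpha")[[1]][1, 2], 0)
})

test_that("correlation follows the Pearson definition", {
  set.seed(2)
  x <- rnorm(1000)
  rec <- rec_from_signals(cbind(x, 2 * x + 3, -x), fs = 250)
  m <- correlation_matrix(rec, band = NULL)[[1]]
  expect_equal(m[1, 2], 1, tolerance = 1e-12)
  expect_equal(m[1, 3], -1, tolerance = 1e-12)
  # two fixed 8-sample vectors against the covariance formula evaluated
  # directly
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(2, 1, 4, 3, 6, 5, 8, 7)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  m2 <- correlation_matrix(rec_from_signals(cbind(a, b), fs = 10),
                           band = NULL)[[1]]
  expect_equal(m2[1, 2], hand, tolerance = 1e-12)
  # zero-variance channel is a hard error naming the channel
  expect_error(
    correlation_matrix(rec_from_signals(cbind(rep(1, 100), rnorm(100)),
                                        fs = 10), band = NULL),
    "E1")
})

test_that("a constant passband lag yields PLI = 1 and coherence 1", {
  fs <- 250
  t <- seq(0, 6, length.out = 1501)[-1501]
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * t - pi / 2)  # quarter-cycle lag
  rec <- rec_from_signals(cbind(x, y), fs = fs)
  expect_equal(pli_matrix(rec, "alpha")[[1]][1, 2], 1)
  expect_gt(plv_matrix(rec, "alpha")[[1]][1, 2], 0.999)
  # coherence ignores a pure delay
  expect_gt(coherence_matrix(rec, "alpha")[[1]][1, 2], 0.999)
})

test_that("phase differences symmetric about zero cancel in the PLI", {
  # alternate the lag sign between epochs: per-trial PLI is 1 each time,
  # but a symmetric within-trial mixture cancels. Build the mixture at the
  # signal level: first half of the trial leads, second half lags.
  fs <- 250
  t <- seq(0, 6, length.out = 1501)[-1501]
  x <- sin(2 * pi * 10 * t)
  lag <- rep(c(pi / 4, -pi / 4), each = 750)
  y <- sin(2 * pi * 10 * t - lag)
  rec <- rec_from_signals(cbind(x, y), fs = fs)
  expect_lt(pli_matrix(rec, "alpha")[[1]][1, 2], 0.1)
})

test_that("null coherence of independent noise matches a plain-R oracle", {
  set.seed(7)
  fs <- 250
  n_rep <- 120
  rec <- white_noise_rec(n_rep, 2, 1500, fs = fs, seed = 7)
  est <- sapply(coherence_matrix(rec, "alpha"), function(m) m[1, 2])
  oracle <- replicate(200, {
    oracle_coherence(rnorm(1500), rnorm(1500), fs, 250, 0.5, 8, 13)
  })
  se <- sqrt(sd(oracle)^2 / length(oracle) + sd(est)^2 / length(est))
  expect_lt(abs(mean(est) - mean(oracle)), 3 * se)
})

test_that("null PLV of independent noise matches a plain-R resampling oracle", {
  set.seed(8)
  rec <- white_noise_rec(120, 2, 1500, seed = 8)
  est <- sapply(suppressWarnings(plv_matrix(rec, band = NULL)),
                function(m) m[1, 2])
  keep <- 126:1375  # same 0.5 s edge trim
  oracle <- replicate(200, {
    p1 <- oracle_phase(rnorm(1500))[keep]
    p2 <- oracle_phase(rnorm(1500))[keep]
    Mod(mean(exp(1i * (p1 - p2))))
  })
  se <- sqrt(sd(oracle)^2 / length(oracle) + sd(est)^2 / length(est))
  expect_lt(abs(mean(est) - mean(oracle)), 3 * se)
})

test_that("phase metrics on unfiltered input warn; coherence needs 2 windows", {
  rec <- white_noise_rec(1, 2, 1500)
  expect_warning(plv_matrix(rec, band = NULL), "broadband")
  expect_error(plv_matrix(rec, band = NULL, on_broadband = "error"),
               "broadband")
  short <- white_noise_rec(1, 2, 250)
  expect_error(coherence_matrix(short, "alpha", window_s = 1),
               "2 averaging windows")
})

test_that("all four metrics are permutation-equivariant, symmetric and in range", {
  sp <- coupling_spec("alpha", data.frame(i = 1, j = 3, strength = 0.7),
                      noise_sd = 0.4)
  rec <- generate_epochs(sp, 2, 6, 250, 4, seed = 21)
  perm <- c(3, 1, 4, 2)
  prec <- rec
  prec$data <- rec$data[, perm, , drop = FALSE]
  for (metric in c("coherence", "correlation", "plv", "pli")) {
    m <- subject_connectivity(rec, metric, "alpha")[[1]]
    pm <- subject_connectivity(prec, metric, "alpha")[[1]]
    expect_equal(unclass(pm), unclass(m)[perm, perm], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_lt(max(abs(m - t(m))), 1e-10)
    rng <- if (metric == "correlation") c(-1, 1) else c(0, 1)
    expect_true(all(m >= rng[1] - 1e-9 & m <= rng[2] + 1e-9))
  }
})

test_that("coherence approaches PLV for constant-amplitude narrowband signals", {
  # amplitude-normalizing the cross-spectrum is what turns coherence into
  # the PLV; on tightly phase-locked constant-envelope tones the two agree
  fs <- 250
  t <- seq(0, 6, length.out = 1501)[-1501]
  set.seed(3)
  x <- sin(2 * pi * 10 * t + 0.2 * sin(2 * pi * 0.3 * t))
  y <- sin(2 * pi * 10 * t + 0.2 * sin(2 * pi * 0.3 * t) - 0.7)
  rec <- rec_from_signals(cbind(x, y), fs = fs)
  coh <- coherence_matrix(rec, "alpha")[[1]][1, 2]
  plv <- plv_matrix(rec, "alpha")[[1]][1, 2]
  expect_lt(abs(coh - plv), 0.05)
})

test_that("subject_connectivity dispatches and tidies whole cohorts", {
  sp <- coupling_spec("alpha", data.frame(i = 1, j = 2, strength = 1),
                      noise_sd = 0.1)
  rec <- generate_epochs(sp, 5, 2, 250, 6, seed = 2, subject_id = "s1",
                         group = "case")
  mats <- subject_connectivity(rec, "plv", "alpha", trim_s = 0.25)
  expect_length(mats, 5)
  expect_true(all(sapply(mats, function(m) dim(m)[1] == 6)))
  expect_true(all(sapply(mats, function(m) m[1, 2] > 0.9)))
  expect_error(subject_connectivity(rec, "nope", "alpha"))

  sp2 <- cohort_spec(n_per_group = 2, n_epochs = 3, epoch_len_s = 2,
                     fs = 250, n_channels = 4,
                     base = coupling_spec("alpha"), seed = 4)
  tbl <- cohort_connectivity(generate_cohort(sp2), "correlation", "alpha")
  expect_equal(nrow(tbl), 4 * 3)
  expect_equal(unique(tbl$metric), "correlation")
  expect_equal(unique(tbl$band), "alpha")
  avg <- average_connectivity(tbl$matrix[tbl$subject_id == "ctrl01"])
  expect_s3_class(avg, "fc_matrix")
  expect_equal(unclass(avg),
               Reduce(`+`, lapply(tbl$matrix[1:3], unclass)) / 3,
               ignore_attr = TRUE)
})
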