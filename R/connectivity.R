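#' Connectivity matrix container
#'
#' An `fc_matrix` is a symmetric n_channels x n_channels numeric matrix with
#' metric/band/subject/trial metadata attached. Coherence, PLV and PLI values
#' lie in \[0, 1\]; correlation in \[-1, 1\] (its sign is kept here and the
#' magnitude is taken at thresholding/imaging time).
#'
#' @param values Symmetric numeric matrix.
#' @param metric One of `"coherence"`, `"correlation"`, `"plv"`, `"pli"`.
#' @param band A [band()] or `NULL`.
#' @param subject_id,trial,block Provenance metadata.
#' @return An `fc_matrix`.
#' @export
fc_matrix <- function(values, metric, band = NULL, subject_id = NA_character_,
                      trial = NA_integer_, block = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  asym <- max(abs(values - t(values)))
  if (asym > 1e-10) stop("matrix is not symmetric (max asymmetry ", asym, ")",
                         call. = FALSE)
  metric <- match.arg(metric, c("coherence", "correlation", "plv", "pli"))
  structure(values, class = c("fc_matrix", "matrix"), metric = metric,
            band = band, subject_id = subject_id, trial = trial,
            block = block)
}

#' @export
print.fc_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<fc_matrix> %s%s, %d x %d (subject %s, trial %s)\n",
              attr(x, "metric"),
              if (is.null(b)) "" else paste0(" / ", b$name),
              nrow(x), ncol(x), attr(x, "subject_id"), attr(x, "trial")))
  invisible(x)
}

# Magnitude view used for thresholding and imaging: correlation is signed,
# everything else already nonnegative.
fc_magnitude <- function(m) {
  if (identical(attr(m, "metric"), "correlation")) abs(unclass(m)) else unclass(m)
}

metric_diagonal <- function(metric) if (metric == "pli") 0 else 1

# Wrap phase differences into (-pi, pi]; required for the sign in the
# phase-lag index to be meaningful.
wrap_phase <- function(d) pi - (pi - d) %% (2 * pi)

# Phase matrix (samples x channels) of one trial via the analytic signal.
trial_phases <- function(rec, trial) {
  x <- t(matrix(rec$data[trial, , ], nrow = n_channels(rec)))
  Arg(analytic_matrix(x))
}

prep_band <- function(rec, band, on_broadband = c("warn", "error")) {
  on_broadband <- match.arg(on_broadband)
  if (is.null(band)) {
    msg <- "no band given: instantaneous phase of broadband signal is ill-defined"
    if (on_broadband == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    return(rec)
  }
  bandpass_filter(rec, band)
}

trim_index <- function(n, fs, trim_s) {
  k <- round(trim_s * fs)
  if (2 * k >= n) stop("edge trim leaves no samples", call. = FALSE)
  (k + 1):(n - k)
}

finish_trials <- function(mats, rec, metric, band) {
  lapply(seq_along(mats), function(tr) {
    fc_matrix(mats[[tr]], metric, band, rec$subject_id, tr, rec$block[tr])
  })
}

#' Per-trial connectivity matrices
#'
#' One symmetric n_channels x n_channels matrix per trial, for each of the
#' four supported metrics:
#'
#' * `plv_matrix()`: phase-locking value, the modulus of the time-averaged
#'   unit phasor of the instantaneous phase difference (analytic-signal
#'   phase of the band-filtered series). 1 = perfect phase locking.
#' * `pli_matrix()`: phase-lag index, the absolute time-average of the sign
#'   of the wrapped phase difference. Insensitive to zero-lag coupling:
#'   0 for phase differences centered on 0 mod pi.
#' * `correlation_matrix()`: Pearson correlation of the band-filtered time
#'   series within the trial.
#' * `coherence_matrix()`: magnitude of the window-averaged cross-spectrum
#'   normalized by the auto-spectra, estimated with Hann-tapered windows
#'   (default 1 s, 50% overlap) inside the trial and then averaged over the
#'   FFT bins whose center falls in `[f_lo, f_hi)`.
#'
#' For the phase metrics the first and last `trim_s` seconds of each trial
#' are excluded, because the analytic-signal phase is unreliable at epoch
#' edges.
#'
#' @param rec An [eeg_recording()]; filtering to `band` happens internally.
#' @param band Target band (name, [band()], length-2 numeric) or `NULL` to
#'   use the signal as-is (phase metrics then warn, or error when
#'   `on_broadband = "error"`).
#' @param trim_s Edge trim in seconds for the phase metrics.
#' @param on_broadband What to do when a phase metric is asked to run
#'   without a band.
#' @return A list of [fc_matrix()], one per trial.
#' @export
plv_matrix <- function(rec, band = "alpha", trim_s = 0.5,
                       on_broadband = c("warn", "error")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(band)) band <- as_band(band)
  frec <- prep_band(rec, band, on_broadband)
  keep <- trim_index(n_samples(rec), rec$fs, trim_s)
  mats <- lapply(seq_len(n_trials(rec)), function(tr) {
    ph <- trial_phases(frec, tr)[keep, , drop = FALSE]
    z <- exp(1i * ph)
    m <- Mod(t(z) %*% Conj(z)) / nrow(z)
    diag(m) <- 1
    (m + t(m)) / 2
  })
  finish_trials(mats, rec, "plv", band)
}

#' @rdname plv_matrix
#' @export
pli_matrix <- function(rec, band = "alpha", trim_s = 0.5,
                       on_broadband = c("warn", "error")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(band)) band <- as_band(band)
  frec <- prep_band(rec, band, on_broadband)
  keep <- trim_index(n_samples(rec), rec$fs, trim_s)
  nc <- n_channels(rec)
  mats <- lapply(seq_len(n_trials(rec)), function(tr) {
    ph <- trial_phases(frec, tr)[keep, , drop = FALSE]
    m <- matrix(0, nc, nc)
    for (i in seq_len(nc - 1)) {
      d <- wrap_phase(ph[, i] - ph[, (i + 1):nc, drop = FALSE])
      m[i, (i + 1):nc] <- abs(colMeans(sign(d)))
    }
    m + t(m)
  })
  finish_trials(mats, rec, "pli", band)
}

#' @rdname plv_matrix
#' @export
correlation_matrix <- function(rec, band = "alpha") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(band)) band <- as_band(band)
  frec <- if (is.null(band)) rec else bandpass_filter(rec, band)
  mats <- lapply(seq_len(n_trials(rec)), function(tr) {
    x <- t(frec$data[tr, , , drop = TRUE])
    sds <- apply(x, 2, sd)
    if (any(sds < .Machine$double.eps)) {
      stop("zero-variance channel(s) in trial ", tr, ": ",
           paste(rec$channel_labels[sds < .Machine$double.eps],
                 collapse = ", "), call. = FALSE)
    }
    m <- cor(x)
    diag(m) <- 1
    (m + t(m)) / 2
  })
  finish_trials(mats, rec, "correlation", band)
}

#' @rdname plv_matrix
#' @param window_s Welch window length in seconds (coherence only).
#' @param overlap Fractional window overlap (coherence only).
#' @export
coherence_matrix <- function(rec, band = "alpha", window_s = 1,
                             overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- as_band(band)
  check_band_nyquist(band, rec$fs)
  fs <- rec$fs
  win <- round(window_s * fs)
  step <- max(1, round(win * (1 - overlap)))
  n <- n_samples(rec)
  starts <- seq(1, n - win + 1, by = step)
  if (length(starts) < 2) {
    stop("coherence needs at least 2 averaging windows per trial ",
         "(single-segment coherence is degenerately 1)", call. = FALSE)
  }
  freqs <- (seq_len(win) - 1) * fs / win
  bins <- which(freqs >= band$f_lo & freqs < band$f_hi & freqs <= fs / 2)
  if (!length(bins)) {
    stop("no FFT bin centers inside band with a ", window_s,
         " s window", call. = FALSE)
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))  # Hann
  nc <- n_channels(rec)
  mats <- lapply(seq_len(n_trials(rec)), function(tr) {
    x <- t(rec$data[tr, , , drop = TRUE])
    # spectra[w, c, b]
    spec <- array(0i, dim = c(length(starts), nc, length(bins)))
    for (w in seq_along(starts)) {
      seg <- x[starts[w]:(starts[w] + win - 1), , drop = FALSE] * taper
      f <- stats::mvfft(seg)
      spec[w, , ] <- t(f[bins, , drop = FALSE])
    }
    acc <- matrix(0, nc, nc)
    for (b in seq_along(bins)) {
      xb <- spec[, , b, drop = TRUE]
      if (!is.matrix(xb)) xb <- matrix(xb, ncol = nc)
      s <- t(xb) %*% Conj(xb)          # S[x, y] = sum_w X_x conj(X_y)
      p <- Re(diag(s))
      acc <- acc + Mod(s) / sqrt(outer(p, p))
    }
    m <- acc / length(bins)
    diag(m) <- 1
    (m + t(m)) / 2
  })
  finish_trials(mats, rec, "coherence", band)
}

#' Dispatch one metric over a subject's trials
#'
#' @param rec An [eeg_recording()].
#' @param metric `"coherence"`, `"correlation"`, `"plv"` or `"pli"`.
#' @param band Target band.
#' @param ... Passed to the metric function.
#' @return A list of [fc_matrix()], one per trial.
#' @export
subject_connectivity <- function(rec, metric, band = "alpha", ...) {
  metric <- match.arg(metric, c("coherence", "correlation", "plv", "pli"))
  fn <- switch(metric,
               coherence = coherence_matrix,
               correlation = correlation_matrix,
               plv = plv_matrix,
               pli = pli_matrix)
  fn(rec, band = band, ...)
}

#' Connectivity for a whole cohort, in tidy form
#'
#' @param cohort A list of [eeg_recording()]s (e.g. [generate_cohort()]).
#' @inheritParams subject_connectivity
#' @return A tibble with columns `subject_id`, `group`, `trial`, `block`,
#'   `metric`, `band` and a `matrix` list-column of [fc_matrix()].
#' @export
cohort_connectivity <- function(cohort, metric, band = "alpha", ...) {
  rows <- purrr::map_dfr(cohort, function(rec) {
    mats <- subject_connectivity(rec, metric, band, ...)
    tibble::tibble(
      subject_id = rec$subject_id, group = rec$group,
      trial = seq_along(mats), block = rec$block,
      metric = metric,
      band = if (is.null(band)) NA_character_ else as_band(band)$name,
      matrix = mats)
  })
  rows
}

#' Average connectivity matrices
#'
#' Element-wise mean of a list of [fc_matrix()] (e.g. a subject's trials),
#' keeping the metadata of the first.
#'
#' @param mats List of [fc_matrix()].
#' @return An [fc_matrix()].
#' @export
average_connectivity <- function(mats) {
  stopifnot(length(mats) >= 1)
  acc <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  fc_matrix(acc, attr(mats[[1]], "metric"), attr(mats[[1]], "band"),
            attr(mats[[1]], "subject_id"), NA_integer_,
            attr(mats[[1]], "block"))
}
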