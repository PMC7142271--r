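#' Specify band-limited coupling between channels
#'
#' A coupling specification describes how synthetic multichannel signals are
#' coupled inside one frequency band. Every channel carries an independent
#' narrowband stochastic oscillator (band-filtered Gaussian noise, so phase
#' and amplitude fluctuate and none of the connectivity metrics saturates);
#' for each listed pair a shared carrier is mixed into both channels with
#' weight `strength`, and the second channel's copy is rotated by `lag`
#' radians via the analytic signal. Broadband Gaussian noise with standard
#' deviation `noise_sd` (relative to the unit-variance carriers) is added to
#' every channel.
#'
#' With `strength = 1` and `noise_sd = 0` the two channels of a pair share
#' their phase exactly up to the stated lag, so the downstream phase-locking
#' value is 1 and, for a lag of pi/2, the phase-lag index is also 1. With
#' `strength = 0` channels are independent.
#'
#' @param band Target band (name, `band` object, or length-2 numeric, Hz).
#' @param pairs Data frame with columns `i`, `j` (1-based channel indices),
#'   `strength` in \[0, 1\] and `lag` in \[0, 2*pi). May be `NULL` (no
#'   coupling).
#' @param noise_sd Standard deviation of additive broadband noise.
#' @param amplitude_corr If `TRUE`, both members of each coupled pair are
#'   modulated by a shared slowly varying positive amplitude envelope.
#' @return A `coupling_spec` object.
#' @examples
#' coupling_spec("alpha", data.frame(i = 1, j = 2, strength = 1, lag = pi / 2))
#' @export
coupling_spec <- function(band = "alpha", pairs = NULL, noise_sd = 0.5,
                          amplitude_corr = FALSE) {
  band <- as_band(band)
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(), j = integer(),
                        strength = numeric(), lag = numeric())
  }
  pairs <- as.data.frame(pairs)
  if (!all(c("i", "j", "strength") %in% names(pairs))) {
    stop("`pairs` needs columns i, j, strength (and optionally lag)",
         call. = FALSE)
  }
  if (is.null(pairs$lag)) pairs$lag <- 0
  if (any(pairs$i == pairs$j)) {
    stop("coupling pairs must connect distinct channels (i != j)",
         call. = FALSE)
  }
  if (any(pairs$strength < 0 | pairs$strength > 1)) {
    stop("coupling strength must lie in [0, 1]", call. = FALSE)
  }
  if (any(pairs$lag < 0 | pairs$lag >= 2 * pi)) {
    stop("phase lag must lie in [0, 2*pi)", call. = FALSE)
  }
  stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  structure(list(band = band, pairs = pairs, noise_sd = noise_sd,
                 amplitude_corr = isTRUE(amplitude_corr)),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec> band %s [%g, %g) Hz, %d coupled pair(s), noise_sd %g%s\n",
              x$band$name, x$band$f_lo, x$band$f_hi, nrow(x$pairs),
              x$noise_sd, if (x$amplitude_corr) ", shared envelopes" else ""))
  invisible(x)
}

# Internal: unit-variance narrowband carriers (band-filtered white noise),
# one per column. Generates with 1 s of padding on each side, filters
# forward-backward, then crops the interior so the carriers have no filter
# edge transient.
narrowband_carriers <- function(n, k, band, fs) {
  pad <- round(fs)
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  x <- filtfilt_cpp(bf$b, bf$a,
                    matrix(rnorm((n + 2 * pad) * k), n + 2 * pad, k))
  x <- x[(pad + 1):(pad + n), , drop = FALSE]
  sds <- apply(x, 2, sd)
  sds[sds < .Machine$double.eps] <- 1
  sweep(x, 2, sds, "/")
}

hilbert_weights <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

# Internal: analytic signal via the frequency-domain Hilbert method.
analytic_signal <- function(x) {
  n <- length(x)
  fft(fft(x) * hilbert_weights(n), inverse = TRUE) / n
}

# Column-wise analytic signal of a samples x channels matrix.
analytic_matrix <- function(x) {
  n <- nrow(x)
  stats::mvfft(stats::mvfft(x) * hilbert_weights(n), inverse = TRUE) / n
}

# Internal: rotate a narrowband signal's phase by `lag` radians.
rotate_phase <- function(x, lag) {
  if (lag == 0) return(x)
  Re(analytic_signal(x) * exp(-1i * lag))
}

# Internal: smooth positive envelope, mean approximately 1.
shared_envelope <- function(n, fs) {
  pad <- round(fs)
  bf <- signal::butter(2, min(0.9, 1 / (fs / 2)), type = "low")
  e <- filtfilt_cpp(bf$b, bf$a,
                    matrix(rnorm(n + 2 * pad), ncol = 1))[(pad + 1):(pad + n), 1]
  s <- sd(e)
  if (s > .Machine$double.eps) e <- e / s
  1 + 0.4 * tanh(e)
}

#' Generate epoched synthetic signals with known coupling
#'
#' Draws `n_epochs` independent epochs of `n_channels` signals according to a
#' [coupling_spec()]. Each epoch regenerates all carriers, so coupled pairs
#' share phase up to the stated lag with a fresh random baseline phase per
#' epoch, and uncoupled channels are independent. Output is deterministic for
#' a fixed `seed`.
#'
#' @param spec A [coupling_spec()].
#' @param n_epochs Number of epochs.
#' @param epoch_len_s Epoch length in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of channels.
#' @param seed Integer seed (required; the generator is a ground-truth
#'   source, so runs must be reproducible).
#' @param subject_id,group,block Metadata forwarded to [eeg_recording()].
#' @return An [eeg_recording()] of dimension
#'   `n_epochs x n_channels x epoch_len_s * fs`.
#' @export
generate_epochs <- function(spec, n_epochs = 30, epoch_len_s = 6, fs = 250,
                            n_channels = 16, seed,
                            subject_id = "S1", group = NA_character_,
                            block = NA_character_) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  check_band_nyquist(spec$band, fs)
  n <- epoch_len_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop("epoch_len_s * fs must be an integer number of samples",
         call. = FALSE)
  }
  n <- round(n)
  pairs <- spec$pairs
  if (nrow(pairs) && max(pairs$i, pairs$j) > n_channels) {
    stop("coupling pair indexes a channel beyond n_channels", call. = FALSE)
  }
  # per-channel total coupled variance must not exceed 1
  w2 <- numeric(n_channels)
  for (p in seq_len(nrow(pairs))) {
    w2[pairs$i[p]] <- w2[pairs$i[p]] + pairs$strength[p]^2
    w2[pairs$j[p]] <- w2[pairs$j[p]] + pairs$strength[p]^2
  }
  if (any(w2 > 1 + 1e-9)) {
    stop("summed squared coupling strengths exceed 1 for some channel",
         call. = FALSE)
  }
  out <- array(0, dim = c(n_epochs, n_channels, n))
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      carriers <- narrowband_carriers(n, n_channels + nrow(pairs),
                                      spec$band, fs)
      x <- sweep(carriers[, seq_len(n_channels), drop = FALSE], 2,
                 sqrt(pmax(0, 1 - w2)), "*")
      for (p in seq_len(nrow(pairs))) {
        s <- carriers[, n_channels + p]
        env <- if (spec$amplitude_corr) shared_envelope(n, fs) else 1
        rho <- pairs$strength[p]
        x[, pairs$i[p]] <- x[, pairs$i[p]] + rho * s * env
        x[, pairs$j[p]] <- x[, pairs$j[p]] +
          rho * rotate_phase(s, pairs$lag[p]) * env
      }
      if (spec$noise_sd > 0) {
        x <- x + spec$noise_sd * matrix(rnorm(n * n_channels), n, n_channels)
      }
      out[ep, , ] <- t(x)
    }
  })
  eeg_recording(out, fs, subject_id = subject_id, group = group,
                block = block)
}

#' Specify a two-group synthetic cohort
#'
#' The default shape mirrors a 48-subject study: two balanced groups of 24
#' subjects, 30 epochs of 6 s sampled at 250 Hz on 128 channels. `base`
#' describes the coupling common to everyone; `effect` lists coupling pairs
#' that replace/extend `base` for the `"case"` group only, so group
#' differences are fully under the caller's control (an empty `effect`
#' makes the groups exchangeable).
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param n_epochs,epoch_len_s,fs,n_channels Epoch geometry, as in
#'   [generate_epochs()].
#' @param base A [coupling_spec()] applied to every subject.
#' @param effect Optional [coupling_spec()]; its pairs override/extend
#'   `base$pairs` for case subjects.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = 24, n_epochs = 30, epoch_len_s = 6,
                        fs = 250, n_channels = 128,
                        base = coupling_spec(), effect = NULL, seed = 1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  stopifnot(inherits(base, "coupling_spec"))
  if (!is.null(effect)) stopifnot(inherits(effect, "coupling_spec"))
  n <- n_epochs * epoch_len_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop("n_epochs * epoch_len_s * fs must be an integer sample count",
         call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, n_epochs = n_epochs,
                 epoch_len_s = epoch_len_s, fs = fs,
                 n_channels = n_channels, base = base, effect = effect,
                 seed = seed),
            class = "cohort_spec")
}

# Internal: merge effect pairs into base pairs (match on unordered (i, j)).
merge_coupling <- function(base, effect) {
  if (is.null(effect) || nrow(effect$pairs) == 0) return(base)
  bp <- base$pairs
  key <- function(df) paste(pmin(df$i, df$j), pmax(df$i, df$j))
  keep <- !(key(bp) %in% key(effect$pairs))
  merged <- rbind(bp[keep, , drop = FALSE], effect$pairs)
  coupling_spec(effect$band, merged, base$noise_sd,
                base$amplitude_corr || effect$amplitude_corr)
}

#' Generate a labeled two-group cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list of [eeg_recording()]s (class `eeg_cohort`), controls first
#'   (`ctrl01`, ...) then cases (`case01`, ...). Trials are split evenly into
#'   `"Neu"` and `"Emo"` blocks.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  case_spec <- merge_coupling(spec$base, spec$effect)
  half <- floor(spec$n_epochs / 2)
  block <- c(rep("Neu", half), rep("Emo", spec$n_epochs - half))
  recs <- vector("list", 2 * spec$n_per_group)
  for (k in seq_len(2 * spec$n_per_group)) {
    is_case <- k > spec$n_per_group
    id <- if (is_case) sprintf("case%02d", k - spec$n_per_group)
          else sprintf("ctrl%02d", k)
    recs[[k]] <- generate_epochs(
      if (is_case) case_spec else spec$base,
      n_epochs = spec$n_epochs, epoch_len_s = spec$epoch_len_s,
      fs = spec$fs, n_channels = spec$n_channels,
      seed = derive_seed(spec$seed, k),
      subject_id = id, group = if (is_case) "case" else "control",
      block = block)
  }
  names(recs) <- vapply(recs, `[[`, "", "subject_id")
  structure(recs, class = "eeg_cohort", spec = spec)
}

#' Reference cohort with an alpha-band coupling difference
#'
#' A ready-made [cohort_spec()] for exercising the full pipeline: both
#' groups share weak alpha-band coupling (`base_strength`) on `n_pairs`
#' disjoint channel pairs; with `effect = TRUE` the case group's coupling on
#' those same pairs is raised to `case_strength`, a clearly separable
#' regime. With `effect = FALSE` the groups are exchangeable, which is the
#' matched null condition for calibration.
#'
#' @param n_per_group,n_channels,n_epochs,epoch_len_s,fs Cohort geometry.
#' @param n_pairs Number of coupled channel pairs (pairs (1,2), (3,4), ...).
#' @param base_strength,case_strength Coupling strengths for the two groups.
#' @param noise_sd Broadband noise level.
#' @param effect If `FALSE`, the case group gets the base coupling too.
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
alpha_coupling_cohort <- function(n_per_group = 12, n_channels = 32,
                                  n_epochs = 30, epoch_len_s = 6, fs = 250,
                                  n_pairs = 10, base_strength = 0.15,
                                  case_strength = 0.85, noise_sd = 0.5,
                                  effect = TRUE, seed = 1) {
  stopifnot(2 * n_pairs <= n_channels)
  pairs <- data.frame(i = seq(1, 2 * n_pairs, by = 2),
                      j = seq(2, 2 * n_pairs, by = 2),
                      strength = base_strength, lag = 0)
  eff <- pairs
  eff$strength <- case_strength
  cohort_spec(n_per_group = n_per_group, n_epochs = n_epochs,
              epoch_len_s = epoch_len_s, fs = fs, n_channels = n_channels,
              base = coupling_spec("alpha", pairs, noise_sd),
              effect = if (effect) coupling_spec("alpha", eff, noise_sd),
              seed = seed)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf(
    "<eeg_cohort> %d subjects (%d per group), %d x %d x %d each @ %g Hz\n",
    length(x), sp$n_per_group, sp$n_epochs, sp$n_channels,
    sp$epoch_len_s * sp$fs, sp$fs))
  invisible(x)
}
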