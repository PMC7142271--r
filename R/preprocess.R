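#' Zero-phase filtering of epoched recordings
#'
#' `broadband_filter()` applies the standard acquisition band-pass (0.5-70 Hz
#' by default); `bandpass_filter()` restricts a recording to one rhythm band.
#' Both use a 4th-order Butterworth design applied forward and backward
#' (`signal::filtfilt`), so the passband phase is untouched -- a requirement
#' for the downstream phase-synchronization metrics. Signal length is
#' preserved.
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Band edges in Hz (`hi` must be below Nyquist).
#' @param band A band (name, `band` object or length-2 numeric).
#' @param order Butterworth design order (per pass).
#' @return A filtered [eeg_recording()].
#' @export
broadband_filter <- function(rec, lo = 0.5, hi = 70, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  apply_bandpass(rec, lo, hi, order)
}

#' @rdname broadband_filter
#' @export
bandpass_filter <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- as_band(band)
  apply_bandpass(rec, band$f_lo, band$f_hi, order)
}

apply_bandpass <- function(rec, lo, hi, order = 4) {
  fs <- rec$fs
  if (hi >= fs / 2) {
    stop(sprintf("upper cutoff %g Hz must be below Nyquist (%g Hz)",
                 hi, fs / 2), call. = FALSE)
  }
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi", call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  d <- rec$data
  nch <- dim(d)[2]
  for (tr in seq_len(dim(d)[1])) {
    x <- matrix(d[tr, , ], nrow = nch)  # channels x samples
    d[tr, , ] <- t(filtfilt_cpp(bf$b, bf$a, t(x)))
  }
  out <- rec
  out$data <- d
  out
}

#' Segment a continuous signal into fixed-length epochs
#'
#' Cuts a channels x samples matrix (or a vector, treated as one channel)
#' into epochs of `epoch_len_s` seconds. With `marks`, epochs start at the
#' given sample indices (1-based); marks closer than one epoch length to the
#' end are dropped with a warning. Without marks the signal is tiled
#' uniformly and a partial tail is discarded.
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @param fs Sampling rate in Hz.
#' @param epoch_len_s Epoch length in seconds.
#' @param marks Optional integer vector of epoch start samples.
#' @param ... Metadata forwarded to [eeg_recording()].
#' @return An [eeg_recording()] (possibly with zero trials).
#' @export
segment <- function(x, fs, epoch_len_s = 6, marks = NULL, ...) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x))
  n <- round(epoch_len_s * fs)
  total <- ncol(x)
  if (is.null(marks)) {
    n_ep <- total %/% n
    marks <- if (n_ep > 0) seq(1, by = n, length.out = n_ep) else integer()
    if (n_ep == 0) warning("signal shorter than one epoch; zero epochs")
  } else {
    ok <- marks + n - 1 <= total
    if (any(!ok)) {
      warning(sum(!ok), " mark(s) closer than one epoch length to the end; dropped")
      marks <- marks[ok]
    }
  }
  out <- array(0, dim = c(length(marks), nrow(x), n))
  for (k in seq_along(marks)) {
    out[k, , ] <- x[, marks[k]:(marks[k] + n - 1), drop = FALSE]
  }
  eeg_recording(out, fs, ...)
}
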