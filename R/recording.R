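#' Epoched multichannel recordings
#'
#' An `eeg_recording` holds one subject's epoched signal as a numeric array of
#' dimension trials x channels x samples, together with the sampling rate,
#' channel labels (`E1`...`En` by default), a per-trial block label and
#' subject/group metadata.
#'
#' @param data Numeric array, trials x channels x samples. No NaN/Inf.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param subject_id Subject identifier (character scalar).
#' @param group Group label (e.g. `"control"` / `"case"`), or `NA`.
#' @param block Per-trial block labels (recycled if scalar).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = "S1", group = NA_character_,
                          block = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3-d array (trials x channels x samples)",
         call. = FALSE)
  }
  bad <- which(!is.finite(data))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(data))
    stop(sprintf(
      "non-finite sample in trial %d, channel %d (sample %d)",
      idx[1], idx[2], idx[3]), call. = FALSE)
  }
  n_ch <- dim(data)[2]
  if (is.null(channel_labels)) channel_labels <- paste0("E", seq_len(n_ch))
  if (length(channel_labels) != n_ch) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", n_ch, ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  n_tr <- dim(data)[1]
  block <- rep_len(as.character(block), n_tr)
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, group = group, block = block),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_recording> %s%s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id,
    if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
    d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_trials <- function(rec) dim(rec$data)[1]
n_channels <- function(rec) dim(rec$data)[2]
n_samples <- function(rec) dim(rec$data)[3]

#' Pluggable artifact-cleaning hook
#'
#' The package does not implement artifact removal (ocular/EMG components are
#' usually removed with external ICA tooling before analysis). `clean()`
#' applies a user-supplied function `rec -> rec` and re-validates the result;
#' the default is the identity.
#'
#' @param rec An [eeg_recording()].
#' @param fun A function taking and returning an `eeg_recording`.
#' @return A validated `eeg_recording`.
#' @export
clean <- function(rec, fun = identity) {
  stopifnot(inherits(rec, "eeg_recording"), is.function(fun))
  out <- fun(rec)
  if (!inherits(out, "eeg_recording")) {
    stop("cleaning hook must return an eeg_recording", call. = FALSE)
  }
  eeg_recording(out$data, out$fs, out$channel_labels, out$subject_id,
                out$group, out$block)
}
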