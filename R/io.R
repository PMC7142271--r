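#' Read and write recordings in the package array container
#'
#' The container stores one subject as two files next to each other: a raw
#' little-endian float64 stream `<stem>.bin` holding the trials x channels x
#' samples array in column-major order, and a JSON sidecar `<stem>.json` with
#' the dimensions, sampling rate, channel labels, per-trial block labels and
#' subject/group metadata. [write_cohort()] lays a cohort out as one pair per
#' subject plus a `cohort.json` manifest.
#'
#' @param rec An [eeg_recording()].
#' @param stem File stem (path without extension).
#' @return `write_recording()` returns `stem` invisibly; `read_recording()`
#'   an [eeg_recording()].
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  meta <- list(
    format = "fcnet-array-v1",
    dim = dim(rec$data), fs = rec$fs,
    channel_labels = rec$channel_labels,
    subject_id = rec$subject_id, group = rec$group, block = rec$block)
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_recording
#' @param path Path to a container sidecar/stem or an EDF file.
#' @param format `"auto"` (by extension), `"array"` or `"edf"`.
#' @export
read_recording <- function(path, format = c("auto", "array", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "array"
  }
  if (format == "edf") return(read_edf(path))
  stem <- sub("\\.(json|bin)$", "", path)
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar has no sampling rate", call. = FALSE)
  if (is.null(meta$channel_labels)) {
    stop("sidecar has no channel labels", call. = FALSE)
  }
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  n <- prod(meta$dim)
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("truncated data file for ", stem, call. = FALSE)
  eeg_recording(array(x, dim = meta$dim), meta$fs, meta$channel_labels,
                meta$subject_id, meta$group %||% NA_character_, meta$block)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_recording
#' @param cohort An `eeg_cohort` (list of recordings).
#' @param dir Directory to create/read.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  for (rec in cohort) write_recording(rec, file.path(dir, rec$subject_id))
  jsonlite::write_json(list(format = "fcnet-cohort-v1", subjects = ids),
                       file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "cohort.json"),
                             simplifyVector = TRUE)
  recs <- lapply(man$subjects, function(id) {
    read_recording(file.path(dir, paste0(id, ".json")))
  })
  names(recs) <- man$subjects
  structure(recs, class = "eeg_cohort")
}

# ---- minimal EDF (European Data Format, 16-bit) support ----------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(paste0(s, strrep(" ", width)), 1, width)
}

#' Minimal EDF input/output
#'
#' A small reader/writer for uncompressed 16-bit EDF with one common
#' sampling rate across signals. `read_edf()` returns the continuous signal
#' as a single-trial [eeg_recording()] (use [segment()] to epoch it);
#' `write_edf()` stores a channels x samples matrix with one data record per
#' second. Intended for interchange and testing, not as a full EDF(+)
#' implementation.
#'
#' @param x Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz (integer).
#' @param path Output/input file path.
#' @param labels Channel labels.
#' @return `read_edf()` an [eeg_recording()]; `write_edf()` `path`, invisibly.
#' @export
write_edf <- function(x, fs, path, labels = paste0("E", seq_len(nrow(x)))) {
  stopifnot(is.matrix(x), fs == round(fs), fs >= 1)
  ns <- nrow(x)
  n_rec <- ncol(x) %/% fs
  if (n_rec < 1) stop("signal shorter than one 1-s data record", call. = FALSE)
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  # physical bounds must survive the 8-character ASCII header field, so
  # round them outward to 4 decimals and use the written values for scaling
  pmin_ <- as.numeric(sprintf("%.4f", floor(apply(x, 1, min) * 1e4) / 1e4))
  pmax_ <- as.numeric(sprintf("%.4f", ceiling(apply(x, 1, max) * 1e4) / 1e4))
  if (any(nchar(sprintf("%.4f", c(pmin_, pmax_))) > 8)) {
    stop("signal amplitudes too large for the 8-character EDF header fields",
         call. = FALSE)
  }
  rng <- pmax_ - pmin_
  pmax_[rng == 0] <- pmin_[rng == 0] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("X X X X", 80), edf_field("Startdate X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, w) writeChar(paste0(vapply(vals, edf_field, "", w),
                                            collapse = ""), con, eos = NULL)
  per(labels, 16); per(rep("", ns), 80); per(rep("uV", ns), 8)
  per(sprintf("%.4f", pmin_), 8)
  per(sprintf("%.4f", pmax_), 8)
  per(rep(dmin, ns), 8); per(rep(dmax, ns), 8)
  per(rep("", ns), 80); per(rep(fs, ns), 8); per(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pmin_[s]) / (pmax_[s] - pmin_[s]) * (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header length
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not an EDF file: bad signal count", call. = FALSE)
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16); fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1) {
    stop("signals with mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      out[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[s]) / (dmax[s] - dmin[s]) * (pmax_[s] - pmin_[s]) + pmin_[s]
    }
  }
  eeg_recording(array(out, dim = c(1, ns, ncol(out))), fs,
                channel_labels = labels)
}
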