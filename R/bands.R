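#' Frequency band definitions
#'
#' A band is a half-open frequency interval `[f_lo, f_hi)` in Hz. The default
#' table holds the five canonical EEG rhythms used throughout the package:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-70 Hz.
#'
#' @param name Band name (character scalar).
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return `band()` returns a `band` object; `eeg_bands()` a tibble with one
#'   row per canonical band and a `band` list-column.
#' @examples
#' band("alpha", 8, 13)
#' eeg_bands()
#' @export
band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop("band edges must satisfy 0 < f_lo < f_hi (got [", f_lo, ", ", f_hi,
         "))", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s [%g, %g) Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' @rdname band
#' @export
eeg_bands <- function() {
  defs <- list(
    band("delta", 1, 4),
    band("theta", 4, 8),
    band("alpha", 8, 13),
    band("beta", 13, 30),
    band("gamma", 30, 70)
  )
  tibble::tibble(
    name = vapply(defs, `[[`, "", "name"),
    f_lo = vapply(defs, `[[`, 0, "f_lo"),
    f_hi = vapply(defs, `[[`, 0, "f_hi"),
    band = defs
  )
}

#' @rdname band
#' @param x A `band`, band name (e.g. `"alpha"`), or length-2 numeric.
#' @export
as_band <- function(x) {
  if (inherits(x, "band")) return(x)
  if (is.character(x) && length(x) == 1) {
    tab <- eeg_bands()
    hit <- match(x, tab$name)
    if (is.na(hit)) stop("unknown band name: ", x, call. = FALSE)
    return(tab$band[[hit]])
  }
  if (is.numeric(x) && length(x) == 2) {
    return(band(paste0(x[1], "-", x[2], "Hz"), x[1], x[2]))
  }
  stop("cannot interpret object as a frequency band", call. = FALSE)
}

# Internal: validate a band against a sampling rate.
check_band_nyquist <- function(band, fs) {
  if (band$f_hi > fs / 2) {
    stop(sprintf("band %s upper edge %g Hz is above Nyquist (%g Hz)",
                 band$name, band$f_hi, fs / 2), call. = FALSE)
  }
  invisible(band)
}
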