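#' Row-major upper-triangle vector of a connectivity matrix
#'
#' The strictly-above-diagonal entries read line by line (row-major): for an
#' n x n matrix the result has length n(n-1)/2 -- 8128 for 128 channels.
#' Row-major order matters: it is what places all pairs among the last
#' channels at the tail of the vector, so they are the entries dropped when
#' the vector is squared off into an image.
#'
#' @param m Square symmetric matrix (or [fc_matrix()]).
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
upper_triangle_vector <- function(m) {
  v <- if (inherits(m, "fc_matrix")) fc_magnitude(m) else unclass(m)
  if (!is.matrix(v) || nrow(v) != ncol(v)) {
    stop("need a square matrix", call. = FALSE)
  }
  # row-major: transpose, then take the lower triangle column-wise
  tv <- t(v)
  tv[lower.tri(tv)]
}

#' Square an upper-triangle vector into a single-channel image
#'
#' The image side is the largest integer with `side^2 <= length(vec)`; the
#' first `side^2` elements fill the image row by row and the remaining tail
#' is discarded. For a 128-channel matrix (8128 elements) this gives a
#' 90 x 90 image with a 28-element tail -- exactly the pairs among the last
#' 8 channels.
#'
#' @param vec Numeric vector, length >= 4.
#' @param metric,band,subject_id,trial Metadata carried on the image.
#' @return An `fc_image`: side x side matrix with metadata attributes,
#'   including `n_discarded`.
#' @export
vector_to_square <- function(vec, metric = NA_character_, band = NULL,
                             subject_id = NA_character_,
                             trial = NA_integer_) {
  if (length(vec) < 4) stop("need at least 4 elements", call. = FALSE)
  side <- floor(sqrt(length(vec)))
  kept <- vec[seq_len(side^2)]
  img <- matrix(kept, nrow = side, byrow = TRUE)  # fill row by row
  structure(img, class = c("fc_image", "matrix"),
            metric = metric, band = band, subject_id = subject_id,
            trial = trial, n_discarded = length(vec) - side^2)
}

#' Connectivity matrix to image
#'
#' Composition of [upper_triangle_vector()] and [vector_to_square()]:
#' deterministic and order-preserving (channel renumbering changes the
#' image, since the enumeration follows channel number, not scalp
#' location).
#'
#' @param m An [fc_matrix()] (or plain symmetric matrix).
#' @return An `fc_image`.
#' @export
matrix_to_image <- function(m) {
  vector_to_square(upper_triangle_vector(m),
                   metric = attr(m, "metric") %||% NA_character_,
                   band = attr(m, "band"),
                   subject_id = attr(m, "subject_id") %||% NA_character_,
                   trial = attr(m, "trial") %||% NA_integer_)
}

#' @export
print.fc_image <- function(x, ...) {
  d <- dim(x)
  ch <- if (length(d) == 3) d[3] else 1
  cat(sprintf("<fc_image> %d x %d x %d (%s)\n", d[1], d[2], ch,
              attr(x, "metric")))
  invisible(x)
}

#' Stack three single-band images into an RGB image
#'
#' The three bands with the best single-band classification accuracy form
#' the red, green and blue channels (best = red). All images must share the
#' side and metric and come from distinct bands.
#'
#' @param img_r,img_g,img_b `fc_image`s in channel order R, G, B.
#' @return A 3-channel `fc_image` (side x side x 3) with a `bands`
#'   attribute recording the channel order.
#' @export
stack_three_bands <- function(img_r, img_g, img_b) {
  imgs <- list(img_r, img_g, img_b)
  sides <- vapply(imgs, function(i) nrow(i), 0)
  if (length(unique(sides)) != 1) stop("image sides differ", call. = FALSE)
  metrics <- vapply(imgs, function(i) as.character(attr(i, "metric")), "")
  if (length(unique(metrics)) != 1) {
    stop("images come from different metrics", call. = FALSE)
  }
  band_names <- vapply(imgs, function(i) {
    b <- attr(i, "band")
    if (is.null(b)) NA_character_ else b$name
  }, "")
  if (!anyNA(band_names) && length(unique(band_names)) != 3) {
    stop("the three channels must come from distinct bands", call. = FALSE)
  }
  arr <- array(0, dim = c(sides[1], sides[1], 3))
  for (k in 1:3) arr[, , k] <- unclass(imgs[[k]])
  structure(arr, class = c("fc_image", "array"),
            metric = metrics[1], bands = band_names,
            subject_id = attr(img_r, "subject_id"),
            trial = attr(img_r, "trial"),
            n_discarded = attr(img_r, "n_discarded"))
}

#' Image side for a channel count
#'
#' Largest integer whose square fits inside the strict upper triangle:
#' `floor(sqrt(n(n-1)/2))`; 90 for n = 128.
#'
#' @param n_channels Number of channels.
#' @return Integer image side.
#' @export
image_side <- function(n_channels) {
  floor(sqrt(n_channels * (n_channels - 1) / 2))
}

#' Add images to a tidy connectivity table
#'
#' Maps [matrix_to_image()] over the `matrix` list-column of a
#' [cohort_connectivity()] tibble.
#'
#' @param fc_tbl Tibble with a `matrix` list-column.
#' @return The tibble with an added `image` list-column.
#' @export
connectivity_images <- function(fc_tbl) {
  fc_tbl$image <- lapply(fc_tbl$matrix, matrix_to_image)
  fc_tbl
}
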