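#' Plot ROC curves of a CV result
#'
#' One curve per repeat (shaded) plus the vertically averaged mean curve,
#' the usual way repeated-CV ROCs are displayed.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  pts <- object$roc
  grid <- seq(0, 1, by = 0.01)
  mean_tpr <- sapply(split(pts, pts$repeat_), function(d) {
    stats::approx(d$fpr, d$tpr, xout = grid, ties = max, rule = 2)$y
  })
  mean_df <- tibble::tibble(fpr = grid, tpr = rowMeans(mean_tpr))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(ggplot2::aes(group = .data$repeat_),
                       alpha = 0.25, colour = "steelblue") +
    ggplot2::geom_line(data = mean_df, linewidth = 1, colour = "firebrick") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean AUC %.3f over %d repeat(s)",
                      object$mean_auc, object$repeats)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold sweep
#'
#' Small-world index (or another metric column) as a function of threshold.
#'
#' @param sweep A [threshold_sweep()] tibble, optionally with extra grouping
#'   columns (e.g. `group`).
#' @param y Column to draw (default `"S"`).
#' @param colour Optional grouping column name.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, y = "S", colour = NULL) {
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(x = .data$threshold, y = .data[[y]]))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_line()
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  }
  p + ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "Threshold T", y = y) +
    ggplot2::theme_minimal()
}

#' Plot a group-difference graph
#'
#' Thresholds the absolute difference of two connectivity matrices and draws
#' the surviving edges on a circular channel layout -- a quick 2-D view of
#' where two groups' average connectivity differs.
#'
#' @param mA,mB Connectivity matrices ([fc_matrix()] or plain).
#' @param threshold Edge shown when `|A - B| > threshold`.
#' @param labels Channel labels.
#' @return A ggplot object.
#' @export
plot_difference_graph <- function(mA, mB, threshold = 0.1,
                                  labels = NULL) {
  a <- if (inherits(mA, "fc_matrix")) fc_magnitude(mA) else mA
  b <- if (inherits(mB, "fc_matrix")) fc_magnitude(mB) else mB
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a)
  labels <- labels %||% paste0("E", seq_len(n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble::tibble(x = cos(ang), y = sin(ang), label = labels)
  d <- abs(a - b)
  idx <- which(upper.tri(d) & d > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    x = nodes$x[idx[, 1]], y = nodes$y[idx[, 1]],
    xend = nodes$x[idx[, 2]], yend = nodes$y[idx[, 2]],
    weight = d[idx])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "firebrick", size = 2) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
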