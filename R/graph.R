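#' Threshold a connectivity matrix into a binary graph
#'
#' An edge is placed between channels i and j iff the connectivity value
#' strictly exceeds `threshold` (values exactly equal to the threshold give
#' no edge). Correlation is thresholded on its magnitude; the diagonal is
#' ignored.
#'
#' @param m An [fc_matrix()] or plain symmetric matrix.
#' @param threshold Threshold T in (0, 1).
#' @return A `binary_graph`: list with `adjacency` (0/1 symmetric matrix,
#'   zero diagonal), `threshold` and source metadata.
#' @export
binarize <- function(m, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  v <- if (inherits(m, "fc_matrix")) fc_magnitude(m) else unclass(m)
  adj <- (v > threshold) * 1L
  diag(adj) <- 0L
  structure(list(adjacency = adj, threshold = threshold,
                 metric = attr(m, "metric"),
                 band = attr(m, "band")),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (T = %g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold))
  invisible(x)
}

as_bg <- function(g) {
  if (inherits(g, "binary_graph")) return(g)
  if (is.matrix(g)) {
    return(structure(list(adjacency = (g != 0) * 1L, threshold = NA_real_),
                     class = "binary_graph"))
  }
  stop("expected a binary_graph or adjacency matrix", call. = FALSE)
}

bg_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Clustering coefficient
#'
#' Per node, the fraction of realized edges among its neighbours,
#' `2 e_i / (k_i (k_i - 1))`; nodes with fewer than 2 neighbours get 0. The
#' network value `C` is the mean over all nodes.
#'
#' @param g A `binary_graph` (or adjacency matrix).
#' @return List with `node` (per-node values) and `C` (mean).
#' @export
clustering_coefficient <- function(g) {
  g <- as_bg(g)
  ci <- igraph::transitivity(bg_igraph(g), type = "local", isolates = "zero")
  ci[is.na(ci)] <- 0
  list(node = ci, C = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered node pairs. Pairs in
#' different components (infinite distance) are excluded from the mean and
#' counted in `excluded_pairs`; an edgeless graph has no defined L.
#'
#' @param g A `binary_graph` (or adjacency matrix).
#' @return List with `L` and `excluded_pairs`.
#' @export
characteristic_path_length <- function(g) {
  g <- as_bg(g)
  if (sum(g$adjacency) == 0) {
    stop("path length undefined for an edgeless graph", call. = FALSE)
  }
  d <- igraph::distances(bg_igraph(g))
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  list(L = mean(off[finite]), excluded_pairs = sum(!finite))
}

#' Random-network reference values
#'
#' Generates `n_random` uniform random graphs with the same node and edge
#' count as `g` (an Erdos-Renyi G(n, m) null: the connected node pairs are
#' chosen completely at random) and returns the means of their clustering
#' coefficient and path length. Disconnected references use the same
#' finite-pairs path-length convention.
#'
#' @param g A `binary_graph`.
#' @param n_random Number of reference graphs.
#' @param seed Integer seed (results are deterministic per seed).
#' @return List with `Cr` and `Lr`.
#' @export
random_reference <- function(g, n_random = 20, seed = 1) {
  g <- as_bg(g)
  n <- nrow(g$adjacency)
  m <- sum(g$adjacency) / 2
  if (m < 1) stop("need at least one edge", call. = FALSE)
  cs <- numeric(n_random)
  ls <- numeric(n_random)
  with_seed(seed, {
    for (k in seq_len(n_random)) {
      r <- igraph::sample_gnm(n, m)
      ci <- igraph::transitivity(r, type = "local", isolates = "zero")
      ci[is.na(ci)] <- 0
      cs[k] <- mean(ci)
      d <- igraph::distances(r)
      off <- d[row(d) != col(d)]
      ls[k] <- mean(off[is.finite(off)])
    }
  })
  list(Cr = mean(cs), Lr = mean(ls))
}

#' Small-world index
#'
#' `gamma = C / Cr`, `lambda = L / Lr`, `S = gamma / lambda`. `S > 1` is the
#' usual simple indicator of small-world organization.
#'
#' @param C,L Observed clustering coefficient and path length.
#' @param Cr,Lr Random-reference means (must be > 0).
#' @return List with `gamma`, `lambda`, `S`.
#' @export
small_world_index <- function(C, L, Cr, Lr) {
  if (!isTRUE(Cr > 0) || !isTRUE(Lr > 0)) {
    stop("small-world index undefined: random-reference Cr/Lr not positive",
         call. = FALSE)
  }
  gamma <- C / Cr
  lambda <- L / Lr
  list(gamma = gamma, lambda = lambda, S = gamma / lambda)
}

#' Full graph metrics for one binary graph
#'
#' @param g A `binary_graph`.
#' @param n_random,seed Passed to [random_reference()].
#' @return One-row tibble: `C`, `L`, `Cr`, `Lr`, `gamma`, `lambda`, `S`,
#'   `excluded_pairs`, plus a `node_clustering` list-column.
#' @export
graph_metrics <- function(g, n_random = 20, seed = 1) {
  g <- as_bg(g)
  cc <- clustering_coefficient(g)
  pl <- characteristic_path_length(g)
  rr <- random_reference(g, n_random, seed)
  sw <- if (rr$Cr > 0 && rr$Lr > 0) {
    small_world_index(cc$C, pl$L, rr$Cr, rr$Lr)
  } else {
    list(gamma = NA_real_, lambda = NA_real_, S = NA_real_)
  }
  tibble::tibble(C = cc$C, L = pl$L, Cr = rr$Cr, Lr = rr$Lr,
                 gamma = sw$gamma, lambda = sw$lambda, S = sw$S,
                 excluded_pairs = pl$excluded_pairs,
                 node_clustering = list(cc$node))
}

#' Threshold step for a metric
#'
#' 0.025 for coherence, correlation and PLV; 0.005 for the PLI (whose values
#' are much smaller, so the sweep needs a finer grid).
#'
#' @param metric Metric name.
#' @return Step size.
#' @export
threshold_step <- function(metric) {
  metric <- match.arg(metric, c("coherence", "correlation", "plv", "pli"))
  if (metric == "pli") 0.005 else 0.025
}

#' Sweep graph metrics over the full threshold range
#'
#' Binarizes `m` at every interior threshold of the metric's grid
#' (`seq(step, 1 - step, by = step)` with [threshold_step()]) and computes
#' [graph_metrics()] at each. Thresholds where a metric is undefined (e.g.
#' an edgeless graph at high T) are kept as rows of `NA` rather than
#' failing.
#'
#' @param m An [fc_matrix()].
#' @param metric Metric name; defaults to the matrix's own metric.
#' @param n_random,seed Passed to [random_reference()].
#' @return A tibble with one row per threshold.
#' @export
threshold_sweep <- function(m, metric = attr(m, "metric"), n_random = 20,
                            seed = 1) {
  step <- threshold_step(metric)
  grid <- seq(step, 1 - step + 1e-12, by = step)
  grid <- grid[grid > 0 & grid < 1]
  empty <- tibble::tibble(C = NA_real_, L = NA_real_, Cr = NA_real_,
                          Lr = NA_real_, gamma = NA_real_,
                          lambda = NA_real_, S = NA_real_,
                          excluded_pairs = NA_integer_,
                          node_clustering = list(NULL))
  rows <- lapply(seq_along(grid), function(k) {
    g <- binarize(m, grid[k])
    row <- if (sum(g$adjacency) == 0) empty else {
      graph_metrics(g, n_random, derive_seed(seed, k))
    }
    dplyr::mutate(row, threshold = grid[k], n_edges = sum(g$adjacency) / 2,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Per-electrode group comparison of clustering coefficients
#'
#' Two-sample t-test per electrode on subject-level node clustering values
#' (rows = subjects, columns = electrodes), as used to localize group
#' differences at a fixed threshold (typically T = 0.15). Flags follow the
#' convention `"**"` for p < 0.05 and `"*"` for 0.05 <= p < 0.1; an optional
#' FDR-adjusted column is included.
#'
#' @param groupA,groupB Numeric matrices, subjects x electrodes.
#' @param labels Electrode labels (defaults to `E1`...).
#' @return Tibble with `electrode`, group means, `t`, `p`, `p_fdr`,
#'   `direction` (sign of mean A - mean B) and `flag`.
#' @export
group_node_ttest <- function(groupA, groupB,
                             labels = paste0("E", seq_len(ncol(groupA)))) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            ncol(groupA) == ncol(groupB))
  if (nrow(groupA) < 2 || nrow(groupB) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  res <- lapply(seq_len(ncol(groupA)), function(j) {
    a <- groupA[, j]; b <- groupB[, j]
    if (sd(a) < 1e-15 && sd(b) < 1e-15) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
    }
    tibble::tibble(electrode = labels[j], mean_A = mean(a), mean_B = mean(b),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$p_fdr <- stats::p.adjust(out$p, method = "fdr")
  out$direction <- sign(out$mean_A - out$mean_B)
  out$flag <- ifelse(out$p < 0.05, "**", ifelse(out$p < 0.1, "*", ""))
  out
}

#' Subject-level node clustering at one threshold
#'
#' Averages each subject's trial matrices, binarizes at `threshold` and
#' returns the per-electrode clustering coefficients -- the subjects x
#' electrodes matrix consumed by [group_node_ttest()].
#'
#' @param fc_tbl A [cohort_connectivity()] tibble (optionally pre-filtered,
#'   e.g. to one block).
#' @param threshold Threshold T.
#' @return List of two matrices, one per group level.
#' @export
subject_node_clustering <- function(fc_tbl, threshold = 0.15) {
  split_tbl <- split(fc_tbl, fc_tbl$subject_id)
  rows <- lapply(split_tbl, function(s) {
    m <- average_connectivity(s$matrix)
    ci <- clustering_coefficient(binarize(m, threshold))$node
    list(group = s$group[1], ci = ci)
  })
  groups <- vapply(rows, `[[`, "", "group")
  mats <- lapply(unique(groups), function(g) {
    do.call(rbind, lapply(rows[groups == g], `[[`, "ci"))
  })
  names(mats) <- unique(groups)
  mats
}
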