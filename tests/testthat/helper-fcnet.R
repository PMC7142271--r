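# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; oracles deliberately avoid the
# package's own code paths.

# -- tiny recordings -----------------------------------------------------

# recording holding given channel signals (samples x channels), one trial
rec_from_signals <- function(x, fs = 250, ...) {
  x <- as.matrix(x)
  eeg_recording(array(t(x), dim = c(1, ncol(x), nrow(x))), fs, ...)
}

white_noise_rec <- function(n_trials, n_channels, n_samples, fs = 250,
                            seed = 1) {
  set.seed(seed)
  eeg_recording(array(rnorm(n_trials * n_channels * n_samples),
                      dim = c(n_trials, n_channels, n_samples)), fs)
}

# -- graph oracles (brute force, no igraph) ------------------------------

# per-node clustering by direct triangle counting
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    e <- sum(adj[nb, nb]) / 2
    ci[i] <- 2 * e / (k * (k - 1))
  }
  ci
}

# all-pairs shortest paths by repeated BFS; Inf for disconnected pairs
oracle_path_length <- function(adj) {
  n <- nrow(adj)
  dists <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] != 0)) {
          if (d[v] > d[u] + 1) {
            d[v] <- d[u] + 1
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    dists[s, ] <- d
  }
  off <- dists[row(dists) != col(dists)]
  mean(off[is.finite(off)])
}

random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(runif(sum(up)) < p)
  a + t(a)
}

# -- independent CNN reference (double precision, plain R) ----------------

ref_conv <- function(a, W, b) {
  d <- dim(a)
  K <- dim(W)[4]
  ap <- array(0, dim = c(d[1] + 2, d[2] + 2, d[3]))
  ap[2:(d[1] + 1), 2:(d[2] + 1), ] <- a
  out <- array(0, dim = c(d[1], d[2], K))
  for (k in seq_len(K)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- 0
    for (c in seq_len(d[3])) for (ki in 1:3) for (kj in 1:3) {
      s <- s + ap[i + ki - 1, j + kj - 1, c] * W[ki, kj, c, k]
    }
    out[i, j, k] <- s + b[k]
  }
  out
}

ref_forward <- function(w, xn) {
  a1 <- pmax(ref_conv(xn, w$W1, w$b1), 0)
  a2 <- pmax(ref_conv(a1, w$W2, w$b2), 0)
  d <- dim(a2)
  H2 <- d[1] / 2
  p <- array(0, dim = c(H2, d[2] / 2, d[3]))
  for (k in seq_len(d[3])) for (i in seq_len(H2)) for (j in seq_len(d[2] / 2))
    p[i, j, k] <- max(a2[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), k])
  f <- as.vector(p)
  z3 <- drop(f %*% w$W3) + w$b3
  a3 <- pmax(z3, 0)
  z4 <- drop(a3 %*% w$W4) + w$b4
  e <- exp(z4 - max(z4))
  e / sum(e)
}

ref_loss <- function(w, x, y) {
  l <- 0
  for (n in seq_along(y)) {
    xn <- array(x[, , , n], dim = dim(x)[1:3])
    pr <- ref_forward(w, xn)
    l <- l - log(pr[y[n] + 1])
  }
  l / length(y)
}

# jitter weights off the ReLU kink so finite differences are meaningful
offset_weights <- function(w, sd = 0.05) {
  lapply(w, function(p) {
    p + sd * array(rnorm(length(p)),
                   dim = if (is.null(dim(p))) length(p) else dim(p))
  })
}

# -- independent spectral estimators (plain R) ---------------------------

# Welch magnitude coherence of two vectors, Hann taper, band bins [lo, hi)
oracle_coherence <- function(x, y, fs, win, overlap, lo, hi) {
  step <- round(win * (1 - overlap))
  starts <- seq(1, length(x) - win + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  freqs <- (seq_len(win) - 1) * fs / win
  bins <- which(freqs >= lo & freqs < hi & freqs <= fs / 2)
  sxy <- complex(real = numeric(length(bins)))
  sxx <- numeric(length(bins))
  syy <- numeric(length(bins))
  for (s in starts) {
    fx <- fft(x[s:(s + win - 1)] * taper)[bins]
    fy <- fft(y[s:(s + win - 1)] * taper)[bins]
    sxy <- sxy + fx * Conj(fy)
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
  }
  mean(Mod(sxy) / sqrt(sxx * syy))
}

# analytic phase by direct FFT Hilbert (plain R)
oracle_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}
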