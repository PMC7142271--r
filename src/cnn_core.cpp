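// Core of the connectivity-image CNN:
// conv3x3(pad 1) -> ReLU -> conv3x3(pad 1) -> ReLU -> maxpool 2x2/2 ->
// FC -> ReLU -> dropout -> FC -> softmax.
// Single precision throughout; convolutions via im2col + sgemm.
// cnn_batch_cpp exposes one forward(+backward) pass for testing and
// prediction; cnn_train_cpp runs the whole Adam training loop without
// crossing the R boundary per batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::frowvec;

struct NetParams {
  fmat W1, W2, W3, W4;
  frowvec b1, b2, b3, b4;
};

struct Dims {
  int H, W, C;            // input geometry
  int K1, K2, FH, NC;     // filters, hidden, classes
  int H2, W2, D;          // pooled geometry, flattened dim
};

static Dims infer_dims(const NetParams& p, int H, int W, int C) {
  Dims d;
  d.H = H; d.W = W; d.C = C;
  d.K1 = p.W1.n_cols; d.K2 = p.W2.n_cols;
  d.FH = p.W3.n_cols; d.NC = p.W4.n_cols;
  d.H2 = H / 2; d.W2 = W / 2;
  d.D = d.H2 * d.W2 * d.K2;
  if ((int)p.W1.n_rows != 9 * C) stop("W1 rows != 9 * in_channels");
  if ((int)p.W2.n_rows != 9 * d.K1) stop("W2 rows != 9 * conv_filters");
  if ((int)p.W3.n_rows != d.D)
    stop("W3 rows (%d) do not match pooled dim (%d)", (int)p.W3.n_rows, d.D);
  return d;
}

// Gather selected images (0-based idx) from an R double array (H, W, C, N)
// into a zero-padded float cube (H+2, W+2, C*n), slice s = n*C + c.
static fcube pad_gather(const double* x, int H, int W, int C,
                        const std::vector<int>& idx) {
  const int n = idx.size();
  const size_t img = (size_t)H * W * C;
  fcube P(H + 2, W + 2, C * n, arma::fill::zeros);
  for (int k = 0; k < n; ++k) {
    const double* src = x + img * idx[k];
    for (int c = 0; c < C; ++c) {
      fmat& sl = P.slice(k * C + c);
      for (int j = 0; j < W; ++j) {
        float* dst = sl.colptr(j + 1) + 1;
        for (int i = 0; i < H; ++i) dst[i] = (float)src[i];
        src += H;
      }
    }
  }
  return P;
}

// cols(r, q): r = n*HW + j*H + i, q = c*9 + kj*3 + ki
static void im2col(const fcube& P, int H, int W, int C, int N, fmat& cols) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int q = c * 9 + kj * 3 + ki;
        float* dst = cols.colptr(q);
        for (int n = 0; n < N; ++n) {
          const fmat& sl = P.slice(n * C + c);
          for (int j = 0; j < W; ++j)
            std::memcpy(dst + n * HW + j * H, sl.colptr(j + kj) + ki,
                        H * sizeof(float));
        }
      }
}

static void col2im_add(const fmat& cols, int H, int W, int C, int N,
                       fcube& P) {
  const int HW = H * W;
  P.zeros();
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        const int q = c * 9 + kj * 3 + ki;
        const float* src = cols.colptr(q);
        for (int n = 0; n < N; ++n) {
          fmat& sl = P.slice(n * C + c);
          for (int j = 0; j < W; ++j) {
            float* dst = sl.colptr(j + kj) + ki;
            const float* s = src + n * HW + j * H;
            for (int i = 0; i < H; ++i) dst[i] += s[i];
          }
        }
      }
}

static fcube mat_to_cube(const fmat& out, int H, int W, int K, int N) {
  const int HW = H * W;
  fcube Y(H, W, K * N);
  for (int k = 0; k < K; ++k) {
    const float* src = out.colptr(k);
    for (int n = 0; n < N; ++n)
      std::memcpy(Y.slice(n * K + k).memptr(), src + n * HW,
                  HW * sizeof(float));
  }
  return Y;
}

static fmat cube_to_mat(const fcube& Y, int H, int W, int K, int N) {
  const int HW = H * W;
  fmat out(HW * N, K);
  for (int k = 0; k < K; ++k) {
    float* dst = out.colptr(k);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst + n * HW, Y.slice(n * K + k).memptr(),
                  HW * sizeof(float));
  }
  return out;
}

struct Cache {
  fmat cols1, cols2;
  fcube A1, A2;
  fmat Ft, Z3, D3, prob;
  arma::umat amax;
  int N;
};

// Forward pass for a padded input cube; drop == nullptr disables dropout.
static void forward(const NetParams& p, const Dims& d, const fcube& P0,
                    int N, const fmat* drop, Cache& c) {
  const int H = d.H, W = d.W, HW = H * W;
  c.N = N;
  c.cols1.set_size(HW * N, 9 * d.C);
  im2col(P0, H, W, d.C, N, c.cols1);
  fmat out1 = c.cols1 * p.W1;
  out1.each_row() += p.b1;
  out1.transform([](float v) { return v > 0.f ? v : 0.f; });
  c.A1 = mat_to_cube(out1, H, W, d.K1, N);

  fcube P1(H + 2, W + 2, d.K1 * N, arma::fill::zeros);
  for (int s = 0; s < d.K1 * N; ++s)
    P1.slice(s).submat(1, 1, H, W) = c.A1.slice(s);
  c.cols2.set_size(HW * N, 9 * d.K1);
  im2col(P1, H, W, d.K1, N, c.cols2);
  fmat out2 = c.cols2 * p.W2;
  out2.each_row() += p.b2;
  out2.transform([](float v) { return v > 0.f ? v : 0.f; });
  c.A2 = mat_to_cube(out2, H, W, d.K2, N);

  const int H2 = d.H2, W2 = d.W2, HW2 = H2 * W2;
  fcube Pool(H2, W2, d.K2 * N);
  c.amax.set_size(HW2, d.K2 * N);
  for (int s = 0; s < d.K2 * N; ++s) {
    const fmat& a = c.A2.slice(s);
    fmat& pl = Pool.slice(s);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        float best = a(i0, j0);
        int bi = i0, bj = j0;
        if (a(i0 + 1, j0) > best) { best = a(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (a(i0, j0 + 1) > best) { best = a(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (a(i0 + 1, j0 + 1) > best) { best = a(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        pl(i, j) = best;
        c.amax(j * H2 + i, s) = (arma::uword)(bj * H + bi);
      }
  }
  c.Ft.set_size(d.D, N);
  for (int n = 0; n < N; ++n) {
    float* dst = c.Ft.colptr(n);
    for (int k = 0; k < d.K2; ++k)
      std::memcpy(dst + k * HW2, Pool.slice(n * d.K2 + k).memptr(),
                  HW2 * sizeof(float));
  }

  c.Z3 = c.Ft.t() * p.W3;
  c.Z3.each_row() += p.b3;
  c.D3 = c.Z3;
  c.D3.transform([](float v) { return v > 0.f ? v : 0.f; });
  if (drop) c.D3 %= *drop;
  fmat Z4 = c.D3 * p.W4;
  Z4.each_row() += p.b4;
  c.prob = Z4;
  for (int n = 0; n < N; ++n) {
    float mx = c.prob.row(n).max();
    double s = 0;
    for (int k = 0; k < d.NC; ++k) s += std::exp((double)(c.prob(n, k) - mx));
    for (int k = 0; k < d.NC; ++k)
      c.prob(n, k) = (float)(std::exp((double)(c.prob(n, k) - mx)) / s);
  }
}

static double loss_of(const Cache& c, const int* y) {
  double loss = 0;
  for (int n = 0; n < c.N; ++n)
    loss -= std::log(std::max((double)c.prob(n, y[n]), 1e-12));
  return loss / c.N;
}

static void backward(const NetParams& p, const Dims& d, const Cache& c,
                     const int* y, const fmat* drop, NetParams& g) {
  const int N = c.N, H = d.H, W = d.W, HW2 = d.H2 * d.W2;
  fmat dZ4 = c.prob;
  for (int n = 0; n < N; ++n) dZ4(n, y[n]) -= 1.f;
  dZ4 /= (float)N;
  g.W4 = c.D3.t() * dZ4;
  g.b4 = arma::sum(dZ4, 0);
  fmat dD3 = dZ4 * p.W4.t();
  if (drop) dD3 %= *drop;
  for (arma::uword i = 0; i < dD3.n_elem; ++i)
    if (c.Z3[i] <= 0.f) dD3[i] = 0.f;
  g.W3 = c.Ft * dD3;
  g.b3 = arma::sum(dD3, 0);
  fmat dFt = p.W3 * dD3.t();

  fcube dA2(H, W, d.K2 * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const float* src = dFt.colptr(n);
    for (int k = 0; k < d.K2; ++k) {
      fmat& sl = dA2.slice(n * d.K2 + k);
      const arma::uword* am = c.amax.colptr(n * d.K2 + k);
      const float* s = src + k * HW2;
      for (int q = 0; q < HW2; ++q) sl[am[q]] += s[q];
    }
  }
  for (arma::uword i = 0; i < dA2.n_elem; ++i)
    if (c.A2[i] <= 0.f) dA2[i] = 0.f;

  fmat dOut2 = cube_to_mat(dA2, H, W, d.K2, N);
  g.W2 = c.cols2.t() * dOut2;
  g.b2 = arma::sum(dOut2, 0);
  fmat dcols2 = dOut2 * p.W2.t();
  fcube dP1(H + 2, W + 2, d.K1 * N);
  col2im_add(dcols2, H, W, d.K1, N, dP1);
  fcube dA1(H, W, d.K1 * N);
  for (int s = 0; s < d.K1 * N; ++s)
    dA1.slice(s) = dP1.slice(s).submat(1, 1, H, W);
  for (arma::uword i = 0; i < dA1.n_elem; ++i)
    if (c.A1[i] <= 0.f) dA1[i] = 0.f;
  fmat dOut1 = cube_to_mat(dA1, H, W, d.K1, N);
  g.W1 = c.cols1.t() * dOut1;
  g.b1 = arma::sum(dOut1, 0);
}

static fmat as_fmat(SEXP s) {
  NumericVector v(s);
  SEXP dm = Rf_getAttrib(s, R_DimSymbol);
  int nr, nc;
  if (dm == R_NilValue) { nr = v.size(); nc = 1; }
  else {
    IntegerVector d(dm);
    nr = d[0];
    nc = 1;
    for (int i = 1; i < d.size(); ++i) nc *= d[i];
    if (d.size() == 4) { nr = d[0] * d[1] * d[2]; nc = d[3]; }
  }
  fmat m(nr, nc);
  for (int i = 0; i < nr * nc; ++i) m[i] = (float)v[i];
  return m;
}

static NetParams params_from_list(List w) {
  NetParams p;
  p.W1 = as_fmat(w["W1"]); p.W2 = as_fmat(w["W2"]);
  p.W3 = as_fmat(w["W3"]); p.W4 = as_fmat(w["W4"]);
  p.b1 = as_fmat(w["b1"]).t(); p.b2 = as_fmat(w["b2"]).t();
  p.b3 = as_fmat(w["b3"]).t(); p.b4 = as_fmat(w["b4"]).t();
  return p;
}

static NumericVector to_r(const fmat& m, SEXP dim_template) {
  NumericVector out(m.n_elem);
  for (arma::uword i = 0; i < m.n_elem; ++i) out[i] = m[i];
  out.attr("dim") = Rf_getAttrib(dim_template, R_DimSymbol);
  return out;
}

static List params_to_list(const NetParams& p, List tmpl) {
  return List::create(
    _["W1"] = to_r(p.W1, tmpl["W1"]), _["b1"] = to_r(p.b1.t(), tmpl["b1"]),
    _["W2"] = to_r(p.W2, tmpl["W2"]), _["b2"] = to_r(p.b2.t(), tmpl["b2"]),
    _["W3"] = to_r(p.W3, tmpl["W3"]), _["b3"] = to_r(p.b3.t(), tmpl["b3"]),
    _["W4"] = to_r(p.W4, tmpl["W4"]), _["b4"] = to_r(p.b4.t(), tmpl["b4"]));
}

static std::vector<int> seq_idx(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

// One forward (and optionally backward) pass. labels are 0-based;
// dropmask (N x fc_hidden) already scaled by 1/(1-p), 0 x 0 disables it.
// [[Rcpp::export]]
List cnn_batch_cpp(NumericVector x, IntegerVector xdim, List weights,
                   IntegerVector labels, NumericMatrix dropmask, bool train) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if ((int)x.size() != H * W * C * N) stop("input size mismatch");
  if (H % 2 || W % 2) stop("image side must be even for 2x2 pooling");
  NetParams p = params_from_list(weights);
  Dims d = infer_dims(p, H, W, C);
  fmat drop;
  const bool use_drop = dropmask.nrow() == N && dropmask.ncol() == d.FH;
  if (use_drop) {
    drop.set_size(N, d.FH);
    for (int j = 0; j < d.FH; ++j)
      for (int n = 0; n < N; ++n) drop(n, j) = (float)dropmask(n, j);
  }
  fcube P0 = pad_gather(REAL(x), H, W, C, seq_idx(N));
  Cache c;
  forward(p, d, P0, N, use_drop ? &drop : nullptr, c);
  const bool have_y = labels.size() == N;
  double loss = NA_REAL;
  std::vector<int> y(have_y ? N : 0);
  if (have_y) {
    for (int n = 0; n < N; ++n) y[n] = labels[n];
    loss = loss_of(c, y.data());
  }
  NumericMatrix prob_r(N, d.NC);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < d.NC; ++k) prob_r(n, k) = c.prob(n, k);
  if (!train) return List::create(_["prob"] = prob_r, _["loss"] = loss);
  if (!have_y) stop("training pass needs labels");
  NetParams g;
  backward(p, d, c, y.data(), use_drop ? &drop : nullptr, g);
  return List::create(_["prob"] = prob_r, _["loss"] = loss,
                      _["grads"] = params_to_list(g, weights));
}

static void adam_step(fmat& w, const fmat& g, fmat& m, fmat& v,
                      float lr, float b1, float b2, int t) {
  const float c1 = 1.f - std::pow(b1, (float)t);
  const float c2 = 1.f - std::pow(b2, (float)t);
  const float eps = 1e-8f;
  float* wp = w.memptr(); const float* gp = g.memptr();
  float* mp = m.memptr(); float* vp = v.memptr();
  const arma::uword n = w.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

static double accuracy_on(const NetParams& p, const Dims& d,
                          const double* x, int n, const int* y) {
  int correct = 0;
  Cache c;
  const int chunk = 128;
  for (int s = 0; s < n; s += chunk) {
    const int nb = std::min(chunk, n - s);
    std::vector<int> idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = s + i;
    fcube P0 = pad_gather(x, d.H, d.W, d.C, idx);
    forward(p, d, P0, nb, nullptr, c);
    for (int i = 0; i < nb; ++i) {
      int best = 0;
      for (int k = 1; k < d.NC; ++k)
        if (c.prob(i, k) > c.prob(i, best)) best = k;
      if (best == y[s + i]) ++correct;
    }
  }
  return (double)correct / n;
}

// Full Adam training loop. `order` is an epochs x n matrix of 1-based
// shuffled indices (from R's RNG); dropout masks are drawn from R's RNG
// stream inside (unif_rand), so the whole run is reproducible from the R
// seed. Returns best-epoch weights (by validation accuracy) and history.
// [[Rcpp::export]]
List cnn_train_cpp(NumericVector x, IntegerVector xdim, IntegerVector labels,
                   List weights, NumericVector xval, IntegerVector valdim,
                   IntegerVector vlabels, IntegerMatrix order,
                   double lr, double beta1, double beta2, double dropout_p,
                   int batch) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("image side must be even for 2x2 pooling");
  const int epochs = order.nrow();
  if (order.ncol() != N) stop("order matrix must have one column per sample");
  NetParams p = params_from_list(weights);
  Dims d = infer_dims(p, H, W, C);
  const bool has_val = valdim.size() == 4 && valdim[3] > 0;
  std::vector<int> yv(has_val ? valdim[3] : 0);
  for (size_t i = 0; i < yv.size(); ++i) yv[i] = vlabels[i];
  std::vector<int> yt(N);
  for (int i = 0; i < N; ++i) yt[i] = labels[i];

  NetParams m, v;
  m.W1.zeros(arma::size(p.W1)); v.W1.zeros(arma::size(p.W1));
  m.W2.zeros(arma::size(p.W2)); v.W2.zeros(arma::size(p.W2));
  m.W3.zeros(arma::size(p.W3)); v.W3.zeros(arma::size(p.W3));
  m.W4.zeros(arma::size(p.W4)); v.W4.zeros(arma::size(p.W4));
  m.b1.zeros(p.b1.n_elem); v.b1.zeros(p.b1.n_elem);
  m.b2.zeros(p.b2.n_elem); v.b2.zeros(p.b2.n_elem);
  m.b3.zeros(p.b3.n_elem); v.b3.zeros(p.b3.n_elem);
  m.b4.zeros(p.b4.n_elem); v.b4.zeros(p.b4.n_elem);

  NumericVector tr_loss(epochs), tr_acc(epochs), val_acc(epochs);
  NetParams best = p;
  double best_acc = -1;
  int best_epoch = epochs;
  int step = 0;
  Cache c;
  NetParams g;
  GetRNGstate();
  for (int ep = 0; ep < epochs; ++ep) {
    double lsum = 0;
    int correct = 0;
    for (int s = 0; s < N; s += batch) {
      const int nb = std::min(batch, N - s);
      std::vector<int> idx(nb), yb(nb);
      for (int i = 0; i < nb; ++i) {
        idx[i] = order(ep, s + i) - 1;
        yb[i] = yt[idx[i]];
      }
      fmat drop;
      const bool use_drop = dropout_p > 0;
      if (use_drop) {
        drop.set_size(nb, d.FH);
        const float scale = 1.f / (1.f - (float)dropout_p);
        for (arma::uword i = 0; i < drop.n_elem; ++i)
          drop[i] = unif_rand() >= dropout_p ? scale : 0.f;
      }
      fcube P0 = pad_gather(REAL(x), H, W, C, idx);
      forward(p, d, P0, nb, use_drop ? &drop : nullptr, c);
      lsum += loss_of(c, yb.data()) * nb;
      for (int i = 0; i < nb; ++i) {
        int bk = 0;
        for (int k = 1; k < d.NC; ++k)
          if (c.prob(i, k) > c.prob(i, bk)) bk = k;
        if (bk == yb[i]) ++correct;
      }
      backward(p, d, c, yb.data(), use_drop ? &drop : nullptr, g);
      ++step;
      if (lr > 0) {
        adam_step(p.W1, g.W1, m.W1, v.W1, lr, beta1, beta2, step);
        adam_step(p.W2, g.W2, m.W2, v.W2, lr, beta1, beta2, step);
        adam_step(p.W3, g.W3, m.W3, v.W3, lr, beta1, beta2, step);
        adam_step(p.W4, g.W4, m.W4, v.W4, lr, beta1, beta2, step);
        adam_step(p.b1, g.b1, m.b1, v.b1, lr, beta1, beta2, step);
        adam_step(p.b2, g.b2, m.b2, v.b2, lr, beta1, beta2, step);
        adam_step(p.b3, g.b3, m.b3, v.b3, lr, beta1, beta2, step);
        adam_step(p.b4, g.b4, m.b4, v.b4, lr, beta1, beta2, step);
      }
    }
    tr_loss[ep] = lsum / N;
    tr_acc[ep] = (double)correct / N;
    val_acc[ep] = NA_REAL;
    if (has_val) {
      val_acc[ep] = accuracy_on(p, d, REAL(xval), valdim[3], yv.data());
      if (val_acc[ep] > best_acc) {
        best_acc = val_acc[ep];
        best = p;
        best_epoch = ep + 1;
      }
    }
  }
  PutRNGstate();
  if (!has_val) { best = p; best_epoch = epochs; }
  return List::create(
    _["weights"] = params_to_list(best, weights),
    _["train_loss"] = tr_loss, _["train_acc"] = tr_acc,
    _["val_acc"] = val_acc, _["best_epoch"] = best_epoch);
}
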