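// Zero-phase IIR filtering: forward-backward application of a digital
// filter (b, a) to each column of a matrix, with odd-reflection padding of
// 3 * (n_taps - 1) samples at both ends to suppress edge transients.

#include <Rcpp.h>
using namespace Rcpp;

static void iir(const std::vector<double>& b, const std::vector<double>& a,
                std::vector<double>& x) {
  const int k = b.size();  // == a.size(), a[0] == 1
  std::vector<double> z(k, 0.0);
  for (size_t n = 0; n < x.size(); ++n) {
    const double xn = x[n];
    const double yn = b[0] * xn + z[1];
    for (int i = 1; i < k - 1; ++i)
      z[i] = b[i] * xn + z[i + 1] - a[i] * yn;
    z[k - 1] = b[k - 1] * xn - a[k - 1] * yn;
    x[n] = yn;
  }
}

// [[Rcpp::export]]
NumericMatrix filtfilt_cpp(NumericVector b, NumericVector a,
                           NumericMatrix x) {
  const int nb = b.size(), na = a.size();
  const int k = std::max(nb, na);
  std::vector<double> bb(k, 0.0), aa(k, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] == 0) stop("a[1] must be nonzero");
  for (int i = 0; i < k; ++i) { bb[i] /= aa[0]; }
  for (int i = k - 1; i >= 0; --i) aa[i] /= aa[0];
  const int n = x.nrow(), nc = x.ncol();
  const int L = 3 * (k - 1);
  if (n <= L) stop("signal too short for zero-phase filtering (need > %d samples)", L);
  NumericMatrix out(n, nc);
  std::vector<double> buf(n + 2 * L);
  for (int c = 0; c < nc; ++c) {
    // odd reflection: 2*x[0] - x[L..1], x, 2*x[n-1] - x[n-2..n-1-L]
    for (int i = 0; i < L; ++i) buf[i] = 2 * x(0, c) - x(L - i, c);
    for (int i = 0; i < n; ++i) buf[L + i] = x(i, c);
    for (int i = 0; i < L; ++i)
      buf[L + n + i] = 2 * x(n - 1, c) - x(n - 2 - i, c);
    iir(bb, aa, buf);
    std::reverse(buf.begin(), buf.end());
    iir(bb, aa, buf);
    std::reverse(buf.begin(), buf.end());
    for (int i = 0; i < n; ++i) out(i, c) = buf[L + i];
  }
  out
    .attr("dim") = Dimension(n, nc);
  return out;
}
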