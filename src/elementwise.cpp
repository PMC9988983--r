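// Elementwise helpers on large feature blocks, kept in C++ to avoid
// repeated R-level allocations in the training loop.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector elu_fwd_cpp(NumericVector x) {
  NumericVector y = clone(x);
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (y[i] < 0) y[i] = std::exp(y[i]) - 1.0;
  return y;
}

// gradient through ELU given its output y: 1 where y >= 0, else y + 1
// [[Rcpp::export]]
NumericVector elu_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector d = clone(dy);
  const R_xlen_t n = d.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (y[i] < 0) d[i] *= y[i] + 1.0;
  return d;
}

// column-blocked scale-and-shift: treats x as an (n x C) matrix in column
// order and returns x * a[c] + b[c] per column block.
// [[Rcpp::export]]
NumericVector scale_shift_cpp(NumericVector x, NumericVector a,
                              NumericVector b) {
  const R_xlen_t n = x.size();
  const int C = a.size();
  const R_xlen_t m = n / C;
  NumericVector y(n);
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const R_xlen_t off = (R_xlen_t)c * m;
    for (R_xlen_t i = 0; i < m; ++i) y[off + i] = x[off + i] * ac + bc;
  }
  return y;
}
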