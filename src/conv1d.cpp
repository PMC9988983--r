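// Hot loops of the 1-D convolutional network: same-padded stride-1
// convolution forward/backward over (batch x time x channel) cubes,
// implemented as im2col plus BLAS GEMM.
// Weight layout: W[(j-1)*Cin + ci, co] is the tap j (1..k) connecting input
// channel ci to output channel co.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Build the (B*T) x (k*Cin) im2col matrix from a (B x T x Cin) cube.
// Row b + B*t holds the receptive field of output position t for sample b.
static arma::mat im2col(const arma::cube& X, int k) {
  const int B = X.n_rows, T = X.n_cols, Cin = X.n_slices, p = (k - 1) / 2;
  arma::mat M(B * (size_t)T, (size_t)k * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* src = X.slice(ci).memptr();   // column-major B x T
    for (int j = 0; j < k; ++j) {
      // output t gets input t - p + j  =>  valid t in [p - j, T - 1 + p - j]
      int lo = std::max(0, p - j), hi = std::min(T - 1, T - 1 + p - j);
      if (lo > hi) continue;
      double* dst = M.colptr(j * Cin + ci);
      std::memcpy(dst + (size_t)B * lo, src + (size_t)B * (lo - p + j),
                  sizeof(double) * (size_t)B * (hi - lo + 1));
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b) {
  const int B = X.n_rows, T = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols, k = W.n_rows / Cin;
  if ((int)W.n_rows != k * Cin)
    stop("weight rows not a multiple of input channels");
  arma::mat Y = im2col(X, k) * W;               // (B*T) x Cout
  Y.each_row() += b.t();
  return arma::cube(Y.memptr(), B, T, Cout);    // copies into cube layout
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& X, const arma::cube& dY,
                    const arma::mat& W) {
  const int B = X.n_rows, T = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols, k = W.n_rows / Cin, p = (k - 1) / 2;
  const arma::mat dYm(const_cast<double*>(dY.memptr()), (size_t)B * T, Cout,
                      false, true);
  arma::mat M = im2col(X, k);
  arma::mat dW = M.t() * dYm;
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dM = dYm * W.t();                   // (B*T) x (k*Cin)
  arma::cube dX(B, T, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    double* dst = dX.slice(ci).memptr();
    for (int j = 0; j < k; ++j) {
      int lo = std::max(0, p - j), hi = std::min(T - 1, T - 1 + p - j);
      if (lo > hi) continue;
      const double* src = dM.colptr(j * Cin + ci) + (size_t)B * lo;
      double* d = dst + (size_t)B * (lo - p + j);
      const size_t n = (size_t)B * (hi - lo + 1);
      for (size_t t = 0; t < n; ++t) d[t] += src[t];
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
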