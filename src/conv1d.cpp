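// Dilated 1-D convolution kernels (zero-padded "same" convolutions).
//
// Layout: activations are (L positions x C channels) double matrices; the
// weight of a kernel-size-K convolution is a (K*Cin x Cout) matrix whose row
// blocks correspond to kernel taps in order k = 1..K, with tap offsets
// (k - (K+1)/2) * dilation. This matches the R reference implementation
// (im2col ordering) exactly; these kernels only remove the R-level copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// y(i, :) = sum_k x(i + off_k, :) * W_k + b
// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
arma::mat conv1d_fwd_cpp(const arma::mat& x, const arma::mat& W,
                         const arma::vec& b, int K, int dil) {
  const int L = x.n_rows;
  const int Cin = x.n_cols;
  const int Cout = W.n_cols;
  const int half = (K + 1) / 2;
  arma::mat y(L, Cout, arma::fill::zeros);
  y.each_row() += b.t();
  for (int k = 0; k < K; ++k) {
    const int off = (k + 1 - half) * dil;
    const int i1 = std::max(0, -off);
    const int i2 = std::min(L - 1, L - 1 - off);
    if (i1 > i2) continue;
    y.rows(i1, i2) += x.rows(i1 + off, i2 + off) *
      W.rows(k * Cin, (k + 1) * Cin - 1);
  }
  return y;
}

// Gradients: dx(i+off_k, :) += dy(i, :) * W_k^T ;
// dW_k += x(i+off_k, :)^T dy(i, :) ; db = colsums(dy)
// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(const arma::mat& x, const arma::mat& dy,
                    const arma::mat& W, int K, int dil, bool need_dx) {
  const int L = x.n_rows;
  const int Cin = x.n_cols;
  const int half = (K + 1) / 2;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dx;
  if (need_dx) dx.zeros(L, Cin);
  for (int k = 0; k < K; ++k) {
    const int off = (k + 1 - half) * dil;
    const int i1 = std::max(0, -off);
    const int i2 = std::min(L - 1, L - 1 - off);
    if (i1 > i2) continue;
    dW.rows(k * Cin, (k + 1) * Cin - 1) =
      x.rows(i1 + off, i2 + off).t() * dy.rows(i1, i2);
    if (need_dx) {
      dx.rows(i1 + off, i2 + off) +=
        dy.rows(i1, i2) * W.rows(k * Cin, (k + 1) * Cin - 1).t();
    }
  }
  arma::rowvec db = arma::sum(dy, 0);
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = db.t());
}

// Batch-norm affine transform: (x - mu) * invstd * gamma + beta, columnwise.
// [[Rcpp::export(name = ".bn_affine_cpp")]]
List bn_affine_cpp(const arma::mat& x, const arma::vec& mu,
                   const arma::vec& invstd, const arma::vec& gamma,
                   const arma::vec& beta) {
  arma::mat xhat = x;
  xhat.each_row() -= mu.t();
  xhat.each_row() %= invstd.t();
  arma::mat y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  return List::create(Named("xhat") = xhat, Named("y") = y);
}

// Leaky-ReLU forward / backward.
// [[Rcpp::export(name = ".lrelu_fwd_cpp")]]
arma::mat lrelu_fwd_cpp(const arma::mat& x, double slope) {
  arma::mat y = x;
  y.for_each([slope](arma::mat::elem_type& v) { if (v < 0) v *= slope; });
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd_cpp")]]
arma::mat lrelu_bwd_cpp(const arma::mat& dy, const arma::mat& x,
                        double slope) {
  arma::mat dx = dy;
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    if (x[i] <= 0) dx[i] *= slope;
  }
  return dx;
}
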