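#include <Rcpp.h>
using namespace Rcpp;

// Fused Adam step: updates p, m, v in place and returns p.
// lr_t must already carry the bias-correction factor
// lr * sqrt(1 - beta2^t) / (1 - beta1^t).
// [[Rcpp::export(rng = false)]]
NumericVector adam_step(NumericVector p, NumericVector m, NumericVector v,
                        NumericVector g, double lr_t, double beta1,
                        double beta2, double eps) {
  R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    p[i] -= lr_t * m[i] / (std::sqrt(v[i]) + eps);
  }
  return p;
}

// dH * H * (1 - H): backprop through a sigmoid activation in one pass.
// [[Rcpp::export(rng = false)]]
NumericMatrix sigmoid_backprop(NumericMatrix dH, NumericMatrix H) {
  R_xlen_t n = dH.size();
  NumericMatrix out(dH.nrow(), dH.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    double h = H[i];
    out[i] = dH[i] * h * (1.0 - h);
  }
  return out;
}

// 2 * (Xhat - X) * B2 * Xhat * (1 - Xhat): gradient of the penalised
// reconstruction loss through the output sigmoid, one pass.
// [[Rcpp::export(rng = false)]]
NumericMatrix recon_backprop(NumericMatrix Xhat, NumericMatrix X,
                             NumericMatrix B2) {
  R_xlen_t n = Xhat.size();
  NumericMatrix out(Xhat.nrow(), Xhat.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    double xh = Xhat[i];
    out[i] = 2.0 * (xh - X[i]) * B2[i] * xh * (1.0 - xh);
  }
  return out;
}

// sigmoid(A + bias[col]) in one pass.
// [[Rcpp::export(rng = false)]]
NumericMatrix sigmoid_affine(NumericMatrix A, NumericVector bias) {
  R_xlen_t nr = A.nrow(), nc = A.ncol();
  NumericMatrix out(nr, nc);
  for (R_xlen_t j = 0; j < nc; ++j) {
    double bj = bias[j];
    for (R_xlen_t i = 0; i < nr; ++i) {
      out(i, j) = 1.0 / (1.0 + std::exp(-(A(i, j) + bj)));
    }
  }
  return out;
}
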