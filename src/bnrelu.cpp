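// Fused batch-normalization (+ optional ReLU) kernels.  Single-pass column
// statistics and normalization avoid the allocation churn of doing this with
// R matrix sweeps at training time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-channel (column) mean and biased variance in one pass.
// [[Rcpp::export]]
List cpp_bn_stats(const arma::mat& Y) {
  const arma::uword n = Y.n_rows, c = Y.n_cols;
  arma::vec mu(c), v(c);
  for (arma::uword j = 0; j < c; ++j) {
    const double* y = Y.colptr(j);
    double s = 0, s2 = 0;
    for (arma::uword i = 0; i < n; ++i) { s += y[i]; s2 += y[i] * y[i]; }
    mu[j] = s / n;
    double var = s2 / n - mu[j] * mu[j];
    v[j] = var > 0 ? var : 0;
  }
  return List::create(_["mu"] = mu, _["var"] = v);
}

// out = [relu](gamma * (Y - mu) * invstd + beta)
// [[Rcpp::export]]
arma::mat cpp_bn_relu_fwd(const arma::mat& Y, const arma::vec& mu,
                          const arma::vec& invstd, const arma::vec& gamma,
                          const arma::vec& beta, bool relu) {
  const arma::uword n = Y.n_rows, c = Y.n_cols;
  arma::mat out(n, c);
  for (arma::uword j = 0; j < c; ++j) {
    const double a = gamma[j] * invstd[j];
    const double b = beta[j] - gamma[j] * invstd[j] * mu[j];
    const double* y = Y.colptr(j);
    double* o = out.colptr(j);
    if (relu)
      for (arma::uword i = 0; i < n; ++i) {
        const double t = a * y[i] + b;
        o[i] = t > 0 ? t : 0;
      }
    else
      for (arma::uword i = 0; i < n; ++i) o[i] = a * y[i] + b;
  }
  return out;
}

// Backward through [ReLU +] BN given the pre-BN activations Yc and the
// gradient dOut at the block output.  The ReLU mask is recomputed from the
// affine output sign.  Uses the batch-statistics backward formula
//   dY = invstd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat)).
// [[Rcpp::export]]
List cpp_bn_relu_bwd(const arma::mat& Yc, const arma::mat& dOut,
                     const arma::vec& mu, const arma::vec& invstd,
                     const arma::vec& gamma, const arma::vec& beta,
                     bool relu, bool batch_stats) {
  const arma::uword n = Yc.n_rows, c = Yc.n_cols;
  arma::mat dY(n, c);
  arma::vec dgamma(c), dbeta(c);
  for (arma::uword j = 0; j < c; ++j) {
    const double is = invstd[j], m = mu[j], gm = gamma[j], bt = beta[j];
    const double* y = Yc.colptr(j);
    const double* do_ = dOut.colptr(j);
    double* dy = dY.colptr(j);
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    for (arma::uword i = 0; i < n; ++i) {
      const double xhat = (y[i] - m) * is;
      double g = do_[i];
      if (relu && (gm * xhat + bt) <= 0) g = 0;
      const double dxhat = g * gm;
      dy[i] = dxhat;           // stash; rescaled below
      dg += g * xhat;
      db += g;
      s1 += dxhat;
      s2 += dxhat * xhat;
    }
    dgamma[j] = dg;
    dbeta[j] = db;
    if (batch_stats) {
      const double inv_n = 1.0 / (double)n;
      for (arma::uword i = 0; i < n; ++i) {
        const double xhat = (y[i] - m) * is;
        dy[i] = is * (dy[i] - inv_n * s1 - xhat * inv_n * s2);
      }
    } else {
      for (arma::uword i = 0; i < n; ++i) dy[i] *= is;
    }
  }
  return List::create(_["dY"] = dY, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
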