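// Core numerics of the Matern-5/2 GP surrogate: log marginal likelihood and
// its gradient with respect to log-hyperparameters.  Kept in compiled code
// (hand-rolled element loops, no large temporaries) because it sits in the
// inner loop of hyperparameter fitting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// D: flattened n x n x ng array of per-group squared distances.
// theta: c(log lengthscale per group, log signal_var, log noise_var).
// [[Rcpp::export]]
Rcpp::List gp_lml_grad_cpp(const Rcpp::NumericVector& D, const arma::vec& y,
                           const arma::vec& theta, double jitter,
                           bool want_grad) {
  const int n = y.n_elem;
  const int nn = n * n;
  const int ng = D.size() / nn;
  std::vector<double> inv_ell2(ng);
  for (int g = 0; g < ng; ++g) inv_ell2[g] = std::exp(-2.0 * theta[g]);
  const double sv = std::exp(theta[ng]);
  const double nv = std::exp(theta[ng + 1]);
  const double* d = D.begin();

  mat K(n, n), R(n, n), core(n, n);
  const double five_thirds = 5.0 / 3.0;
  for (int idx = 0; idx < nn; ++idx) {
    double r2 = 0.0;
    for (int g = 0; g < ng; ++g) r2 += d[idx + g * nn] * inv_ell2[g];
    const double a = std::sqrt(5.0 * (r2 > 0.0 ? r2 : 0.0));
    const double e = std::exp(-a);
    const double r = (1.0 + a + a * a / 3.0) * e;
    R[idx] = r;
    K[idx] = sv * r;
    if (want_grad) core[idx] = five_thirds * sv * (1.0 + a) * e;
  }
  K.diag() += nv + jitter;

  mat L;
  if (!chol(L, K, "lower")) {
    return Rcpp::List::create(Rcpp::Named("lml") = -1e10,
                              Rcpp::Named("grad") = Rcpp::NumericVector(ng + 2));
  }
  vec alpha = solve(trimatu(L.t()), solve(trimatl(L), y));
  double lml = -0.5 * dot(y, alpha) - accu(log(L.diag())) -
               0.5 * n * std::log(2.0 * datum::pi);
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("lml") = lml,
                              Rcpp::Named("grad") = R_NilValue);
  }
  mat Linv = inv(trimatl(L));
  mat W = alpha * alpha.t() - Linv.t() * Linv;  // alpha alpha^T - K^{-1}
  vec grad(ng + 2, fill::zeros);
  // d k / d r2 = -(5/6) sv (1 + a) e^{-a}; d r2 / d log ell_g = -2 D_g/ell_g^2
  double gsv = 0.0, gnv = 0.0;
  const double* w = W.memptr();
  const double* cr = core.memptr();
  const double* rr = R.memptr();
  for (int idx = 0; idx < nn; ++idx) {
    const double wc = w[idx] * cr[idx];
    for (int g = 0; g < ng; ++g) grad[g] += wc * d[idx + g * nn] * inv_ell2[g];
    gsv += w[idx] * rr[idx];
  }
  for (int i = 0; i < n; ++i) gnv += W(i, i);
  for (int g = 0; g < ng; ++g) grad[g] *= 0.5;
  grad[ng] = 0.5 * sv * gsv;
  grad[ng + 1] = 0.5 * nv * gnv;
  return Rcpp::List::create(Rcpp::Named("lml") = lml,
                            Rcpp::Named("grad") = grad);
}

// Cross-covariance posterior: mean and latent sd at m query points.
// Dx: flattened n x m x ng array of squared distances training-vs-query.
// [[Rcpp::export]]
Rcpp::List gp_post_cpp(const Rcpp::NumericVector& Dx, int m,
                       const arma::vec& theta, const arma::mat& L,
                       const arma::vec& alpha) {
  const int n = alpha.n_elem;
  const int nm = n * m;
  const int ng = Dx.size() / nm;
  std::vector<double> inv_ell2(ng);
  for (int g = 0; g < ng; ++g) inv_ell2[g] = std::exp(-2.0 * theta[g]);
  const double sv = std::exp(theta[ng]);
  const double* d = Dx.begin();

  mat Kx(n, m);
  for (int idx = 0; idx < nm; ++idx) {
    double r2 = 0.0;
    for (int g = 0; g < ng; ++g) r2 += d[idx + g * nm] * inv_ell2[g];
    const double a = std::sqrt(5.0 * (r2 > 0.0 ? r2 : 0.0));
    Kx[idx] = sv * (1.0 + a + a * a / 3.0) * std::exp(-a);
  }
  vec mu = Kx.t() * alpha;
  mat v = solve(trimatl(L), Kx);
  vec var = sv - sum(square(v), 0).t();
  var.clamp(0.0, datum::inf);
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("sd") = sqrt(var));
}
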