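#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Internal LinUCB kernels. The R-level agent owns the matrices exclusively
// (created inside the constructor), so in-place mutation is safe and avoids
// allocating d x d temporaries on every trial.

// score_a = theta'x + alpha * sqrt(x' Ainv x); also writes u = Ainv x into
// the caller's buffer so the subsequent update can reuse it.
// [[Rcpp::export(name = ".linucbScoreCpp")]]
double linucbScoreCpp(const arma::mat& Ainv, Rcpp::NumericVector theta_,
                      Rcpp::NumericVector x_, double alpha,
                      Rcpp::NumericVector u_) {
  const int d = x_.size();
  const arma::vec x(x_.begin(), d, false, true);
  const arma::vec theta(theta_.begin(), d, false, true);
  arma::vec u(u_.begin(), d, false, true);
  u = Ainv * x;
  double q = arma::dot(x, u);
  if (q < 0.0) q = 0.0;  // guard tiny negative round-off
  return arma::dot(theta, x) + alpha * std::sqrt(q);
}

// Sherman-Morrison step given u = Ainv x (computed before this update):
//   b     += r x
//   Ainv  -= u u' / (1 + x'u)        (manual rank-1, no temporary)
//   theta += r u - ((u'b_old + r u'x) / (1 + x'u)) u   (exact O(d) identity
//            for Ainv_new (b_old + r x) = theta_old + ...)
// [[Rcpp::export(name = ".linucbRank1Cpp")]]
void linucbRank1Cpp(Rcpp::NumericMatrix Ainv_, Rcpp::NumericVector b_,
                    Rcpp::NumericVector theta_, Rcpp::NumericVector x_,
                    Rcpp::NumericVector u_, double r) {
  const int d = Ainv_.nrow();
  arma::mat Ainv(Ainv_.begin(), d, d, false, true);
  arma::vec b(b_.begin(), d, false, true);
  arma::vec theta(theta_.begin(), d, false, true);
  const arma::vec x(x_.begin(), d, false, true);
  const arma::vec u(u_.begin(), d, false, true);

  const double c = 1.0 + arma::dot(x, u);
  const double ub = arma::dot(u, b);
  const double ux = arma::dot(u, x);

  b += r * x;
  for (int j = 0; j < d; ++j) {
    const double uj = u[j] / c;
    double* col = Ainv.colptr(j);
    const double* up = u.memptr();
    for (int i = 0; i < d; ++i) col[i] -= up[i] * uj;
  }
  theta += (r - (ub + r * ux) / c) * u;
}
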