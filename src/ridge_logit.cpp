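#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// L2-penalized logistic regression by iteratively reweighted least
// squares. X excludes the intercept column (added here); the intercept is
// unpenalized. Returns the (p + 1)-vector of coefficients.
// [[Rcpp::export]]
arma::vec ridgeLogitFit(const arma::mat& X, const arma::vec& y,
                        const double lambda, const int maxit,
                        const double tol) {
  const uword n = X.n_rows, p = X.n_cols;
  mat Xd(n, p + 1);
  Xd.col(0).ones();
  if (p > 0) Xd.cols(1, p) = X;
  vec pen(p + 1);
  pen.fill(lambda);
  pen(0) = 0.0;
  vec beta(p + 1, fill::zeros), eta(n, fill::zeros);
  for (int it = 0; it < maxit; ++it) {
    const vec mu = 1.0 / (1.0 + exp(-eta));
    const vec w = clamp(mu % (1.0 - mu), 1e-10, datum::inf);
    const vec z = eta + (y - mu) / w;
    mat Xw = Xd.each_col() % sqrt(w);
    mat H = Xw.t() * Xw;
    H.diag() += pen;
    vec betaNew;
    if (!solve(betaNew, H, Xd.t() * (w % z), solve_opts::likely_sympd)) break;
    const vec etaNew = Xd * betaNew;
    const double delta = abs(betaNew - beta).max();
    beta = betaNew;
    eta = etaNew;
    if (delta < tol) break;
  }
  return beta;
}
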