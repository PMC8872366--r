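// Profiled objective and gradient for the simplex-constrained
// stratified-interaction WQS fit.
//
// Parameter vector: par = (theta_1..theta_{2c}, beta1), where the 52 (=2c)
// weights are per-block softmax(theta) scaled to mass 1/2 -- first c entries
// the boy block, next c the girl block, so the full vector sums to 1 -- and
// beta1 is the reference-stratum index slope (its sign constraint is a box
// bound handled by the optimizer).  Fixing each block's mass at 1/2 removes
// the flat likelihood direction that a free joint simplex would have (block
// masses trade off exactly against the magnitudes of beta1 and beta12).
//
// Given (w, beta1) the remaining coefficients (intercept, Female, WQS:Female,
// covariates) are linear and profiled out by least squares, so the returned
// value is RSS(w, beta1) at the profiled optimum and the gradient follows
// from the envelope theorem.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void unpack(const vec& par, uword c, vec& w, double& beta1) {
  w.set_size(2 * c);
  for (uword b = 0; b < 2; ++b) {
    vec theta = par.subvec(b * c, (b + 1) * c - 1);
    theta -= theta.max();
    vec e = exp(theta);
    w.subvec(b * c, (b + 1) * c - 1) = 0.5 * e / accu(e);
  }
  beta1 = par(2 * c);
}

static vec strat_index(const mat& Q, const vec& x, const vec& w, uword c) {
  vec Wb = Q * w.subvec(0, c - 1);
  vec Wg = Q * w.subvec(c, 2 * c - 1);
  return (1.0 - x) % Wb + x % Wg;
}

// design for the profiled linear part: [1, x, x*W, Z]
static mat lin_design(const vec& x, const vec& W, const mat& Z) {
  const uword n = x.n_elem;
  mat D(n, 3 + Z.n_cols);
  D.col(0).ones();
  D.col(1) = x;
  D.col(2) = x % W;
  if (Z.n_cols > 0) D.cols(3, 2 + Z.n_cols) = Z;
  return D;
}

static bool profile_fit(const mat& D, const vec& r0, vec& gamma, vec& r) {
  mat DtD = D.t() * D;
  vec Dtr = D.t() * r0;
  bool ok = solve(gamma, DtD, Dtr, solve_opts::no_approx);
  if (!ok) return false;
  r = r0 - D * gamma;
  return true;
}

// [[Rcpp::export]]
double wqs_obj_cpp(const arma::vec& par, const arma::mat& Q,
                   const arma::vec& x, const arma::mat& Z,
                   const arma::vec& y) {
  const uword c = Q.n_cols;
  vec w; double beta1;
  unpack(par, c, w, beta1);
  vec W = strat_index(Q, x, w, c);
  vec r0 = y - beta1 * W;
  mat D = lin_design(x, W, Z);
  vec gamma, r;
  if (!profile_fit(D, r0, gamma, r)) return 1e30;
  return dot(r, r);
}

// [[Rcpp::export]]
arma::vec wqs_grad_cpp(const arma::vec& par, const arma::mat& Q,
                       const arma::vec& x, const arma::mat& Z,
                       const arma::vec& y) {
  const uword c = Q.n_cols;
  vec w; double beta1;
  unpack(par, c, w, beta1);
  vec W = strat_index(Q, x, w, c);
  vec r0 = y - beta1 * W;
  mat D = lin_design(x, W, Z);
  vec gamma, r;
  vec g(2 * c + 1, fill::zeros);
  if (!profile_fit(D, r0, gamma, r)) return g;
  const double beta12 = gamma(2);
  // dRSS/dW_i = -2 r_i (beta1 + beta12 x_i); chain to the weight blocks
  vec u = r % (beta1 + beta12 * x);
  vec gw(2 * c);
  gw.subvec(0, c - 1) = -2.0 * (Q.t() * (u % (1.0 - x)));
  gw.subvec(c, 2 * c - 1) = -2.0 * (Q.t() * (u % x));
  // per-block softmax Jacobian (block mass 1/2): with s_b the block's
  // weight-weighted mean gradient, dRSS/dtheta_k = w_k (gw_k - 2 s_b)
  for (uword b = 0; b < 2; ++b) {
    vec wb = w.subvec(b * c, (b + 1) * c - 1);
    vec gb = gw.subvec(b * c, (b + 1) * c - 1);
    double s = dot(wb, gb);
    g.subvec(b * c, (b + 1) * c - 1) = wb % (gb - 2.0 * s);
  }
  g(2 * c) = -2.0 * dot(r, W);
  return g;
}

// Coefficients of the profiled linear part at given (w, beta1):
// (intercept, beta2, beta12, phi...) plus the residual sum of squares.
// [[Rcpp::export]]
Rcpp::List wqs_profile_cpp(const arma::vec& par, const arma::mat& Q,
                           const arma::vec& x, const arma::mat& Z,
                           const arma::vec& y) {
  const uword c = Q.n_cols;
  vec w; double beta1;
  unpack(par, c, w, beta1);
  vec W = strat_index(Q, x, w, c);
  vec r0 = y - beta1 * W;
  mat D = lin_design(x, W, Z);
  vec gamma, r;
  bool ok = profile_fit(D, r0, gamma, r);
  return Rcpp::List::create(
    Rcpp::Named("weights") = w,
    Rcpp::Named("beta1") = beta1,
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("rss") = ok ? dot(r, r) : NA_REAL,
    Rcpp::Named("ok") = ok);
}
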