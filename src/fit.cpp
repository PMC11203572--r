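// Fast GLM fitting for the exhaustive significance-constrained model
// search.  A model space over k predictors has 2^(k + k(k-1)/2) - 1 term
// sets per predictor subset, so the search fits ~1e5 small GLMs; the IRLS
// loop lives here.  Conventions (deviance-based convergence, clamped
// fitted probabilities, classical SEs) mirror stats::glm / stats::lm and
// are verified against them in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct FitResult {
  arma::vec coef;
  arma::vec se;
  double loglik;
  bool ok;         // converged, full rank, finite
  int npar;        // parameters counted by the information criterion
};

static const double MU_EPS = 1e-12;

// Logistic regression by iteratively reweighted least squares.
static FitResult fit_logistic(const arma::mat& X, const arma::vec& y,
                              int maxit, double tol) {
  FitResult res;
  const int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  double dev_old = R_PosInf;
  bool converged = false;
  arma::mat XtWX(p, p);
  arma::vec eta, mu, w, z;
  for (int it = 0; it < maxit; ++it) {
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, MU_EPS, 1.0 - MU_EPS);
    w = mu % (1.0 - mu);
    z = eta + (y - mu) / w;
    XtWX = X.t() * (X.each_col() % w);
    arma::vec XtWz = X.t() * (w % z);
    arma::vec beta_new;
    bool solved = arma::solve(beta_new, XtWX, XtWz,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
    if (!solved || !beta_new.is_finite()) {
      res.ok = false; res.coef = beta; res.se = arma::vec(p, arma::fill::value(NA_REAL));
      res.loglik = NA_REAL; res.npar = p;
      return res;
    }
    beta = beta_new;
    eta = X * beta;
    mu = arma::clamp(1.0 / (1.0 + arma::exp(-eta)), MU_EPS, 1.0 - MU_EPS);
    double dev = -2.0 * arma::accu(y % arma::log(mu) +
                                   (1.0 - y) % arma::log(1.0 - mu));
    if (std::abs(dev - dev_old) / (0.1 + std::abs(dev)) < tol) {
      converged = true;
      dev_old = dev;
      break;
    }
    dev_old = dev;
  }
  // covariance at the final weights
  mu = arma::clamp(1.0 / (1.0 + arma::exp(-X * beta)), MU_EPS, 1.0 - MU_EPS);
  w = mu % (1.0 - mu);
  XtWX = X.t() * (X.each_col() % w);
  arma::mat cov;
  bool inv_ok = arma::inv_sympd(cov, XtWX);
  if (!inv_ok) inv_ok = arma::inv(cov, XtWX);
  res.coef = beta;
  res.se = inv_ok ? arma::sqrt(cov.diag()).eval()
                  : arma::vec(p, arma::fill::value(NA_REAL));
  res.loglik = -dev_old / 2.0;
  res.ok = converged && inv_ok && beta.is_finite() && res.se.is_finite();
  res.npar = p;
  return res;
}

// Ordinary least squares with classical standard errors.
static FitResult fit_linear(const arma::mat& X, const arma::vec& y) {
  FitResult res;
  const int n = X.n_rows, p = X.n_cols;
  arma::mat XtX = X.t() * X;
  arma::vec beta;
  bool solved = arma::solve(beta, XtX, X.t() * y, arma::solve_opts::no_approx);
  if (!solved || !beta.is_finite() || n <= p) {
    res.ok = false; res.coef = arma::vec(p, arma::fill::value(NA_REAL));
    res.se = res.coef; res.loglik = NA_REAL; res.npar = p + 1;
    return res;
  }
  arma::vec resid = y - X * beta;
  double rss = arma::dot(resid, resid);
  double sigma2 = rss / (n - p);
  arma::mat cov;
  bool inv_ok = arma::inv_sympd(cov, XtX);
  if (!inv_ok) inv_ok = arma::inv(cov, XtX);
  res.coef = beta;
  res.se = inv_ok ? arma::sqrt(sigma2 * cov.diag()).eval()
                  : arma::vec(p, arma::fill::value(NA_REAL));
  // Gaussian MLE log-likelihood, matching stats::logLik.lm
  res.loglik = -0.5 * n * (std::log(2.0 * M_PI * rss / n) + 1.0);
  res.ok = inv_ok && res.se.is_finite() && rss >= 0;
  res.npar = p + 1;  // residual variance counts as a parameter
  return res;
}

static double wald_p(double est, double se) {
  if (!std::isfinite(est) || !std::isfinite(se) || se <= 0) return NA_REAL;
  return 2.0 * R::pnorm(-std::fabs(est / se), 0.0, 1.0, 1, 0);
}

// [[Rcpp::export]]
List fit_single_cpp(NumericMatrix X_, NumericVector y_, int family,
                    int maxit = 100, double tol = 1e-10) {
  arma::mat X(X_.begin(), X_.nrow(), X_.ncol(), false);
  arma::vec y(y_.begin(), y_.size(), false);
  FitResult r = (family == 0) ? fit_logistic(X, y, maxit, tol)
                              : fit_linear(X, y);
  NumericVector p(r.coef.n_elem);
  for (size_t j = 0; j < r.coef.n_elem; ++j) p[j] = wald_p(r.coef[j], r.se[j]);
  return List::create(_["coef"] = NumericVector(r.coef.begin(), r.coef.end()),
                      _["se"] = NumericVector(r.se.begin(), r.se.end()),
                      _["wald_p"] = p,
                      _["loglik"] = r.loglik,
                      _["npar"] = r.npar,
                      _["ok"] = r.ok);
}

// Linear least squares from a precomputed Gram system: G = X'X, b = X'y,
// yty = y'y for the full term matrix (intercept first); each mask solves
// the submatrix system, so the per-model cost is independent of n.
static FitResult fit_linear_gram(const arma::mat& G, const arma::vec& b,
                                 double yty, int n) {
  FitResult res;
  const int p = G.n_cols;
  arma::vec beta;
  bool solved = arma::solve(beta, G, b,
                            arma::solve_opts::likely_sympd +
                            arma::solve_opts::no_approx);
  if (!solved || !beta.is_finite() || n <= p) {
    res.ok = false; res.coef = arma::vec(p, arma::fill::value(NA_REAL));
    res.se = res.coef; res.loglik = NA_REAL; res.npar = p + 1;
    return res;
  }
  double rss = yty - 2.0 * arma::dot(beta, b) +
               arma::dot(beta, G * beta);
  if (rss < 0 && rss > -1e-8 * yty) rss = 0;
  double sigma2 = rss / (n - p);
  arma::mat cov;
  bool inv_ok = arma::inv_sympd(cov, G);
  if (!inv_ok) inv_ok = arma::inv(cov, G);
  res.coef = beta;
  res.se = inv_ok ? arma::sqrt(sigma2 * cov.diag()).eval()
                  : arma::vec(p, arma::fill::value(NA_REAL));
  res.loglik = (rss > 0) ? -0.5 * n * (std::log(2.0 * M_PI * rss / n) + 1.0)
                         : R_PosInf;
  res.ok = inv_ok && res.se.is_finite() && rss > 0;
  res.npar = p + 1;
  return res;
}

// Exhaustively fit every nonempty subset of the columns of X (all term
// columns for one predictor subset; the intercept is added internally).
// Returns one row per bitmask 1..2^T-1 with columns:
//   loglik, npar, ok (converged/full-rank/finite, within |coef|,se guard),
//   allsig (every Wald p < alpha, intercept included).
// [[Rcpp::export]]
NumericMatrix exhaustive_fit_cpp(NumericMatrix X_, NumericVector y_,
                                 int family, double alpha = 0.05,
                                 double guard = 1e3, int maxit = 100,
                                 double tol = 1e-10) {
  const int n = X_.nrow(), T = X_.ncol();
  if (T > 25) stop("too many term columns for exhaustive enumeration");
  arma::mat Xall(X_.begin(), n, T, false);
  arma::vec y(y_.begin(), n, false);
  const long n_masks = (1L << T) - 1L;
  NumericMatrix out(n_masks, 4);

  // full Gram system (intercept + all T term columns) for the linear fast path
  arma::mat Xfull(n, T + 1);
  Xfull.col(0).ones();
  Xfull.cols(1, T) = Xall;
  arma::mat Gfull = Xfull.t() * Xfull;
  arma::vec bfull = Xfull.t() * y;
  double yty = arma::dot(y, y);

  arma::mat Xm(n, T + 1);
  Xm.col(0).ones();
  arma::uvec sel(T + 1);
  for (long mask = 1; mask <= n_masks; ++mask) {
    int p = 1;
    sel[0] = 0;
    for (int j = 0; j < T; ++j) {
      if (mask & (1L << j)) { Xm.col(p) = Xall.col(j); sel[p] = j + 1; ++p; }
    }
    FitResult r;
    if (family == 0) {
      arma::mat Xsub = Xm.cols(0, p - 1);
      r = fit_logistic(Xsub, y, maxit, tol);
    } else {
      arma::uvec s = sel.head(p);
      r = fit_linear_gram(Gfull.submat(s, s), bfull.elem(s), yty, n);
    }
    bool sep = false;
    if (r.ok) {
      if (arma::abs(r.coef).max() > guard || r.se.max() > guard) sep = true;
    }
    bool ok = r.ok && !sep;
    bool allsig = ok;
    if (ok) {
      for (int j = 0; j < p; ++j) {
        double pw = wald_p(r.coef[j], r.se[j]);
        if (!std::isfinite(pw) || pw >= alpha) { allsig = false; break; }
      }
    }
    out(mask - 1, 0) = r.loglik;
    out(mask - 1, 1) = r.npar;
    out(mask - 1, 2) = ok ? 1.0 : 0.0;
    out(mask - 1, 3) = allsig ? 1.0 : 0.0;
  }
  return out;
}
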