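// Iteratively reweighted least squares with the Tukey bisquare weight
// function, plus the subject-level bootstrap of the robust partial
// correlation. Lives in C++ because the bootstrap default is 100,000
// resamples per correlation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double mad_scale(const vec& r) {
  vec a = abs(r - median(r));
  return median(a) / 0.6745;
}

struct IrlsFit {
  vec coef;
  vec w;
  vec se;
  bool converged;
  int iterations;
  bool ok;
};

// OLS start; robust scale re-estimated each iteration from the MAD of
// residuals; stop when the max coefficient change drops below `tol`.
static IrlsFit irls_core(const mat& X, const vec& y, double tuning,
                         double tol, int maxit) {
  IrlsFit out;
  out.converged = false;
  out.iterations = 0;
  out.ok = true;
  const uword n = X.n_rows, p = X.n_cols;
  vec b;
  if (!solve(b, X, y, solve_opts::no_approx)) { out.ok = false; return out; }
  vec w(n, fill::ones);
  for (int it = 1; it <= maxit; ++it) {
    out.iterations = it;
    vec r = y - X * b;
    double s = mad_scale(r);
    if (s < 1e-12) { out.converged = true; break; }  // (near) exact fit
    vec u = r / (tuning * s);
    w.zeros();
    uvec in = find(abs(u) < 1.0);
    if (in.n_elem < p) { out.ok = false; break; }
    w(in) = square(1.0 - square(u(in)));
    mat Xw = X.each_col() % sqrt(w);
    vec bn;
    if (!solve(bn, Xw.t() * Xw, X.t() * (w % y), solve_opts::no_approx)) {
      out.ok = false;
      break;
    }
    double delta = abs(bn - b).max();
    b = bn;
    if (delta < tol) { out.converged = true; break; }
  }
  out.coef = b;
  out.w = w;
  // Standard errors from the final weighted least-squares step.
  vec r = y - X * b;
  double s2 = dot(w % r, r) / double(n - p);
  mat cov;
  if (inv_sympd(cov, X.t() * (X.each_col() % w))) {
    out.se = sqrt(s2 * cov.diag());
  } else {
    out.se = vec(p);
    out.se.fill(datum::nan);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List irls_bisquare_cpp(const arma::mat& X, const arma::vec& y,
                             double tuning, double tol, int maxit) {
  IrlsFit f = irls_core(X, y, tuning, tol, maxit);
  if (!f.ok) Rcpp::stop("robust fit failed: design is (weighted) rank deficient");
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = f.coef,
    Rcpp::Named("weights") = f.w,
    Rcpp::Named("se") = f.se,
    Rcpp::Named("converged") = f.converged,
    Rcpp::Named("iterations") = f.iterations);
}

// Robust partial correlation of y with X column 1 (X = [x, covariates, 1]):
// r = sign(b1) * sqrt(t^2 / (t^2 + df)), df = n - p.
static double rpcor_from_fit(const mat& X, const vec& y, double tuning,
                             double tol, int maxit) {
  IrlsFit f = irls_core(X, y, tuning, tol, maxit);
  if (!f.ok || !std::isfinite(f.se(0)) || f.se(0) <= 0.0)
    return datum::nan;
  double t = f.coef(0) / f.se(0);
  double df = double(X.n_rows - X.n_cols);
  double r = std::sqrt(t * t / (t * t + df));
  return f.coef(0) < 0 ? -r : r;
}

// Subject-level bootstrap of the robust partial correlation. Resamples with
// replacement; degenerate resamples (constant x or y) are redrawn and
// counted. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
Rcpp::List boot_rpcor_cpp(const arma::vec& x, const arma::vec& y,
                          const arma::mat& Z, int nboot, double tuning,
                          double tol, int maxit) {
  const uword n = x.n_elem;
  const uword p = 2 + Z.n_cols;
  vec rs(nboot);
  int ndegen = 0;
  mat Xb(n, p);
  Xb.col(p - 1).ones();
  for (int b = 0; b < nboot; ++b) {
    double r = datum::nan;
    for (int tries = 0; tries < 1000; ++tries) {
      uvec idx(n);
      for (uword i = 0; i < n; ++i) {
        uword k = (uword)(unif_rand() * n);
        idx(i) = k >= n ? n - 1 : k;
      }
      vec xb = x(idx), yb = y(idx);
      if (xb.max() - xb.min() < 1e-12 || yb.max() - yb.min() < 1e-12) {
        ++ndegen;
        continue;
      }
      Xb.col(0) = xb;
      if (Z.n_cols > 0) Xb.cols(1, p - 2) = Z.rows(idx);
      r = rpcor_from_fit(Xb, yb, tuning, tol, maxit);
      if (std::isfinite(r)) break;
      ++ndegen;
    }
    rs(b) = r;
    if (b % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("r") = rs,
    Rcpp::Named("n_degenerate") = ndegen);
}
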