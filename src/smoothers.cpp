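// Local weighted least-squares smoothers with a Gaussian kernel.
// Used for the pooled covariance surface, its diagonal, and the
// rotated local-quadratic fit behind the noise-variance estimator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double gkern(double u) { return std::exp(-0.5 * u * u); }

// 2-D local fit with basis {1, ds, dt, ds*dt} (cross = true) or {1, ds, dt}.
// Returns fitted values at targets (t1[m], t2[m]); when want_hat is true the
// targets are assumed to coincide with data points and the hat-diagonal
// (self-influence) is returned alongside, for GCV.
// [[Rcpp::export]]
List lwls2d_cpp(const arma::vec& x1, const arma::vec& x2, const arma::vec& z,
                const arma::vec& t1, const arma::vec& t2,
                double h, bool cross, bool want_hat) {
  const arma::uword N = x1.n_elem, M = t1.n_elem;
  const arma::uword p = cross ? 4 : 3;
  arma::vec fit(M), hat(M, arma::fill::value(NA_REAL));
  fit.fill(NA_REAL);
  arma::mat A(p, p);
  arma::vec b(p);
  double X[4];
  for (arma::uword m = 0; m < M; ++m) {
    A.zeros(); b.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      const double d1 = x1[i] - t1[m], d2 = x2[i] - t2[m];
      const double w = gkern(d1 / h) * gkern(d2 / h);
      if (w < 1e-14) continue;
      X[0] = 1.0; X[1] = d1; X[2] = d2; X[3] = d1 * d2;
      for (arma::uword r = 0; r < p; ++r) {
        b[r] += w * X[r] * z[i];
        for (arma::uword c = r; c < p; ++c) A(r, c) += w * X[r] * X[c];
      }
    }
    A = arma::symmatu(A);
    arma::vec beta;
    if (!arma::solve(beta, A, b, arma::solve_opts::no_approx)) continue;
    fit[m] = beta[0];
    if (want_hat) {
      arma::mat Ai;
      if (arma::inv(Ai, A)) hat[m] = Ai(0, 0);  // kernel weight at self is 1
    }
  }
  return List::create(_["fit"] = fit, _["hat"] = hat);
}

// 1-D local polynomial fit of given degree (1 or 2).
// [[Rcpp::export]]
List lwls1d_cpp(const arma::vec& x, const arma::vec& z,
                const arma::vec& t, double h, int degree, bool want_hat) {
  const arma::uword N = x.n_elem, M = t.n_elem;
  const arma::uword p = (arma::uword)degree + 1;
  arma::vec fit(M), hat(M, arma::fill::value(NA_REAL));
  fit.fill(NA_REAL);
  arma::mat A(p, p);
  arma::vec b(p);
  double X[3];
  for (arma::uword m = 0; m < M; ++m) {
    A.zeros(); b.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      const double d = x[i] - t[m];
      const double w = gkern(d / h);
      if (w < 1e-14) continue;
      X[0] = 1.0; X[1] = d; X[2] = d * d;
      for (arma::uword r = 0; r < p; ++r) {
        b[r] += w * X[r] * z[i];
        for (arma::uword c = r; c < p; ++c) A(r, c) += w * X[r] * X[c];
      }
    }
    A = arma::symmatu(A);
    arma::vec beta;
    if (!arma::solve(beta, A, b, arma::solve_opts::no_approx)) continue;
    fit[m] = beta[0];
    if (want_hat) {
      arma::mat Ai;
      if (arma::inv(Ai, A)) hat[m] = Ai(0, 0);
    }
  }
  return List::create(_["fit"] = fit, _["hat"] = hat);
}

// Local fit along the covariance diagonal in rotated coordinates
// u = (s + t)/sqrt(2), v = (t - s)/sqrt(2): basis {1, u - u0, v^2},
// i.e. locally linear along the diagonal and quadratic perpendicular
// to it. Data are off-diagonal covariance entries; targets are the
// diagonal points (tg, tg) where v = 0.
// [[Rcpp::export]]
arma::vec lwls_diag_quad_cpp(const arma::vec& s, const arma::vec& t,
                             const arma::vec& z, const arma::vec& tg,
                             double h) {
  const arma::uword N = s.n_elem, M = tg.n_elem;
  const double r2 = std::sqrt(2.0);
  arma::vec fit(M, arma::fill::value(NA_REAL));
  arma::mat A(3, 3);
  arma::vec b(3);
  double X[3];
  for (arma::uword m = 0; m < M; ++m) {
    const double u0 = r2 * tg[m];
    A.zeros(); b.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      const double u = (s[i] + t[i]) / r2, v = (t[i] - s[i]) / r2;
      const double w = gkern((u - u0) / h) * gkern(v / h);
      if (w < 1e-14) continue;
      X[0] = 1.0; X[1] = u - u0; X[2] = v * v;
      for (arma::uword r = 0; r < 3; ++r) {
        b[r] += w * X[r] * z[i];
        for (arma::uword c = r; c < 3; ++c) A(r, c) += w * X[r] * X[c];
      }
    }
    A = arma::symmatu(A);
    arma::vec beta;
    if (arma::solve(beta, A, b, arma::solve_opts::no_approx)) fit[m] = beta[0];
  }
  return fit;
}
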