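#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for
//   min_b (1/2n) ||y - X b||^2 + lambda * sum_j w_j |b_j|
// X is expected column-standardized by the R wrapper (the update uses the
// actual column scale c_j = x_j'x_j / n, so unstandardized input still
// converges to the correct minimizer).

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One sweep over the coordinates listed in `idx`; residual r kept in sync.
// Returns the largest absolute coefficient change of the sweep.
static double sweep_coords(const NumericMatrix& X, NumericVector& r,
                           NumericVector& beta, const NumericVector& cnorm,
                           const NumericVector& pen, double lambda,
                           const std::vector<int>& idx) {
  const int n = X.nrow();
  double max_delta = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    const int j = idx[k];
    const double* xj = &X(0, j);
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
    const double cj = cnorm[j];
    if (cj <= 0.0) continue;  // constant column: coefficient stays 0
    const double z = dot / n + cj * beta[j];
    const double bnew = soft(z, lambda * pen[j]) / cj;
    const double delta = bnew - beta[j];
    if (delta != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * delta;
      beta[j] = bnew;
      const double ad = std::fabs(delta);
      if (ad > max_delta) max_delta = ad;
    }
  }
  return max_delta;
}

static void solve_at_lambda(const NumericMatrix& X, NumericVector& r,
                            NumericVector& beta, const NumericVector& cnorm,
                            const NumericVector& pen, double lambda,
                            double tol, int max_sweeps, bool& converged,
                            int& sweeps_used) {
  const int p = X.ncol();
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  converged = false;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    // full sweep
    double d = sweep_coords(X, r, beta, cnorm, pen, lambda, all);
    ++sweeps;
    if (d < tol) { converged = true; break; }
    // iterate on the current active set until stable, then re-check fully
    std::vector<int> act;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
    while (sweeps < max_sweeps) {
      double da = sweep_coords(X, r, beta, cnorm, pen, lambda, act);
      ++sweeps;
      if (da < tol) break;
    }
  }
  sweeps_used = sweeps;
}

// [[Rcpp::export(name = ".cd_lasso")]]
List cd_lasso(const NumericMatrix& X, const NumericVector& y, double lambda,
              const NumericVector& penalty, NumericVector beta_init,
              double tol = 1e-7, int max_sweeps = 100000) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (penalty.size() != p || beta_init.size() != p)
    stop("penalty/beta_init length mismatch");
  NumericVector beta = clone(beta_init);
  NumericVector cnorm(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    cnorm[j] = s / n;
  }
  NumericVector r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0)
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * beta[j];
  }
  bool converged; int sweeps;
  solve_at_lambda(X, r, beta, cnorm, penalty, lambda, tol, max_sweeps,
                  converged, sweeps);
  return List::create(_["beta"] = beta, _["converged"] = converged,
                      _["sweeps"] = sweeps);
}

// Descend a geometric lambda path from lambda_max with warm starts and stop
// at the first lambda whose active set reaches q_target variables. Used by
// stability selection, where the per-subsample penalty is calibrated so
// that about q_target markers are selected.
// [[Rcpp::export(name = ".cd_lasso_path_qstop")]]
List cd_lasso_path_qstop(const NumericMatrix& X, const NumericVector& y,
                         int q_target, int n_lambda = 100,
                         double lambda_min_ratio = 0.01,
                         double tol = 1e-5, int max_sweeps = 10000) {
  const int n = X.nrow(), p = X.ncol();
  if (q_target >= p) stop("q_target must be < number of markers");
  NumericVector cnorm(p);
  double lam_max = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = 0.0, dot = 0.0;
    for (int i = 0; i < n; ++i) { s += X(i, j) * X(i, j); dot += X(i, j) * y[i]; }
    cnorm[j] = s / n;
    const double a = std::fabs(dot) / n;
    if (a > lam_max) lam_max = a;
  }
  NumericVector beta(p), r = clone(y);
  NumericVector pen(p, 1.0);
  const double mult = std::pow(lambda_min_ratio, 1.0 / (n_lambda - 1));
  double lambda = lam_max;
  int q = 0;
  bool reached = false;
  for (int step = 0; step < n_lambda; ++step) {
    lambda *= mult;  // lambda_max itself selects nothing
    bool conv; int sw;
    solve_at_lambda(X, r, beta, cnorm, pen, lambda, tol, max_sweeps, conv, sw);
    q = 0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) ++q;
    if (q >= q_target) { reached = true; break; }
  }
  IntegerVector sel(q);
  int k = 0;
  for (int j = 0; j < p; ++j) if (beta[j] != 0.0) sel[k++] = j + 1;
  return List::create(_["selected"] = sel, _["lambda"] = lambda,
                      _["q"] = q, _["reached_target"] = reached);
}
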