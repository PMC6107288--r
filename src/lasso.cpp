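#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lasso solvers in "covariance" (Gram) form: the problem is
//   min_b  (1/2) b' G b - b' c + lambda * ||b||_1
// with G = X'X/n and c = X'y/n precomputed once per data set.  Residual
// inner products are maintained incrementally (the covariance update of
// Friedman et al.'s cyclical coordinate descent), never by re-scanning X.

static inline double soft(double z, double lambda) {
  if (z > lambda) return z - lambda;
  if (z < -lambda) return z + lambda;
  return 0.0;
}

// One cyclic pass over the given coordinates (ascending index order);
// v = G b is kept up to date incrementally.  Returns the maximum absolute
// coefficient change of the pass.
static double cd_pass(const double* G, int p, const double* c,
                      double lambda, double* b, double* v,
                      int skip, const int* idx, int nidx) {
  double maxdiff = 0.0;
  for (int t = 0; t < nidx; ++t) {
    const int j = idx ? idx[t] : t;
    if (j == skip) continue;
    const double* Gj = G + (size_t)j * p;
    const double gjj = Gj[j];
    if (gjj <= 0.0) continue;
    const double z = c[j] - v[j] + gjj * b[j];
    const double bnew = soft(z, lambda) / gjj;
    const double d = bnew - b[j];
    if (d != 0.0) {
      b[j] = bnew;
      for (int k = 0; k < p; ++k) v[k] += Gj[k] * d;
      const double ad = std::fabs(d);
      if (ad > maxdiff) maxdiff = ad;
    }
  }
  return maxdiff;
}

// Full solve with the active-set strategy: converge on the current
// non-zero set between full verification passes.  Returns true on
// convergence; *iters accumulates the number of passes taken.
static bool cd_solve(const double* G, int p, const double* c,
                     double lambda, double* b, double* v,
                     int skip, double tol, int max_iter, int* iters) {
  std::vector<int> active;
  active.reserve(p);
  int it = 0;
  while (it < max_iter) {
    const double md = cd_pass(G, p, c, lambda, b, v, skip, nullptr, p);
    ++it;
    if (md < tol) { if (iters) *iters += it; return true; }
    active.clear();
    for (int j = 0; j < p; ++j) if (j != skip && b[j] != 0.0) active.push_back(j);
    while (it < max_iter) {
      const double mda = cd_pass(G, p, c, lambda, b, v, skip,
                                 active.data(), (int)active.size());
      ++it;
      if (mda < tol) break;
    }
  }
  if (iters) *iters += it;
  return false;
}

// [[Rcpp::export]]
List cd_lasso_cpp(NumericMatrix G, NumericVector c, double lambda,
                  NumericVector beta0, double tol, int max_iter) {
  const int p = G.ncol();
  NumericVector b = clone(beta0);
  NumericVector v(p);
  const double* Gp = G.begin();
  for (int j = 0; j < p; ++j) {
    if (b[j] != 0.0) {
      const double* Gj = Gp + (size_t)j * p;
      for (int k = 0; k < p; ++k) v[k] += Gj[k] * b[j];
    }
  }
  int it = 0;
  const bool converged = cd_solve(Gp, p, c.begin(), lambda, b.begin(),
                                  v.begin(), -1, tol, max_iter, &it);
  return List::create(_["beta"] = b, _["iter"] = it,
                      _["converged"] = converged);
}

// Nodewise regressions of every column on the rest, in Gram form.
// S is the p x p second-moment matrix X'X/n of centered data.  For node i
// the sub-problem Gram matrix is S with row/column i masked out, so no
// submatrices are copied.  mode 0 = plain lasso at fixed lambda,
// mode 1 = scaled lasso (lambda = lambda0 * sigma_hat iterated to a fixed
// point of sigma_hat = RMS residual).  Beta0 supplies warm starts
// (column i = coefficients for node i, diagonal ignored/zero).
// [[Rcpp::export]]
List nodewise_cpp(NumericMatrix S, int n, int mode, double lambda,
                  double lambda0, NumericMatrix Beta0, double tol,
                  int max_iter, double outer_tol, int outer_max_iter,
                  double sigma_floor) {
  const int p = S.ncol();
  NumericMatrix Beta(p, p);
  NumericVector sigma(p), lambda_used(p);
  LogicalVector converged(p);
  IntegerVector degenerate(0);

  const double* Sp = S.begin();
  for (int i = 0; i < p; ++i) {
    std::vector<double> b(p, 0.0), v(p, 0.0);
    for (int j = 0; j < p; ++j) {
      if (j != i && Beta0(j, i) != 0.0) b[j] = Beta0(j, i);
    }
    for (int j = 0; j < p; ++j) {
      if (b[j] == 0.0) continue;
      const double* Sj = Sp + (size_t)j * p;
      const double bj = b[j];
      for (int k = 0; k < p; ++k) v[k] += Sj[k] * bj;
    }
    const double* ci = Sp + (size_t)i * p;  // column i of S
    bool conv = false;
    double lam = lambda, sig = 0.0;

    if (mode == 0) {
      conv = cd_solve(Sp, p, ci, lam, b.data(), v.data(), i, tol,
                      max_iter, nullptr);
      double rss = ci[i];
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0) rss += b[j] * (v[j] - 2.0 * ci[j]);
      sig = std::sqrt(std::max(rss, 0.0));
    } else {
      // scaled lasso: alternate the lasso solve with the noise-scale update
      sig = std::sqrt(std::max(ci[i], 0.0));
      if (sig <= sigma_floor) { degenerate.push_back(i + 1); sig = sigma_floor; }
      for (int out = 0; out < outer_max_iter; ++out) {
        lam = lambda0 * sig;
        conv = cd_solve(Sp, p, ci, lam, b.data(), v.data(), i, tol,
                        max_iter, nullptr);
        double rss = ci[i];
        for (int j = 0; j < p; ++j)
          if (b[j] != 0.0) rss += b[j] * (v[j] - 2.0 * ci[j]);
        const double signew = std::sqrt(std::max(rss, 0.0));
        const double d = std::fabs(signew - sig);
        sig = signew;
        if (sig <= sigma_floor) { degenerate.push_back(i + 1); break; }
        if (d < outer_tol) break;
      }
    }
    for (int j = 0; j < p; ++j) Beta(j, i) = (j == i) ? 0.0 : b[j];
    sigma[i] = sig;
    lambda_used[i] = lam;
    converged[i] = conv;
  }
  return List::create(_["beta"] = Beta, _["sigma"] = sigma,
                      _["lambda_used"] = lambda_used,
                      _["converged"] = converged,
                      _["degenerate"] = degenerate);
}

// Theta' * Sigma * Theta visiting only the non-zero entries of Theta's
// columns: with s non-zeros per column the cost is O(s p^2), not O(p^3).
// [[Rcpp::export]]
NumericMatrix sparse_quadform_cpp(NumericMatrix Theta, NumericMatrix Sigma) {
  const int p = Theta.nrow(), q = Theta.ncol();
  // M = Sigma * Theta, accumulated over non-zeros of each Theta column
  NumericMatrix M(p, q);
  for (int j = 0; j < q; ++j) {
    for (int k = 0; k < p; ++k) {
      const double t = Theta(k, j);
      if (t != 0.0) for (int r = 0; r < p; ++r) M(r, j) += Sigma(r, k) * t;
    }
  }
  // out = Theta' * M, again over non-zeros of Theta columns
  NumericMatrix out(q, q);
  for (int j = 0; j < q; ++j) {
    for (int k = 0; k < p; ++k) {
      const double t = Theta(k, j);
      if (t != 0.0) for (int cidx = 0; cidx < q; ++cidx)
        out(j, cidx) += t * M(k, cidx);
    }
  }
  return out;
}

// Instrumented variant counting multiply operations, used to verify the
// O(s p^2) claim on small instances.
// [[Rcpp::export]]
double sparse_quadform_opcount(NumericMatrix Theta, NumericMatrix Sigma) {
  const int p = Theta.nrow(), q = Theta.ncol();
  double ops = 0.0;
  for (int j = 0; j < q; ++j)
    for (int k = 0; k < p; ++k)
      if (Theta(k, j) != 0.0) ops += p + q;
  return ops;
}
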