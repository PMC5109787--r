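#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Penalized binomial logistic regression by IRLS with cyclic coordinate
// descent on the penalized weighted least-squares subproblem.
//
// Objective (intercept unpenalized):
//   -(1/N) sum_i [ y_i eta_i - log(1 + exp(eta_i)) ]
//   + lambda1 * sum_j w_j [ (1-alpha)/2 beta_j^2 + alpha |beta_j| ]
//   + lambda2 * beta' M beta
//
// The fusion quadratic enters each coordinate update exactly: for coordinate
// j it contributes 2*lambda2*M_jj to the curvature and
// 2*lambda2*sum_{k != j} M_jk beta_k to the gradient (M symmetric).
// An infinite l1 weight excludes the coordinate from the solve entirely.
//
// Coordinates are screened with the sequential strong rule
// |g_j| > alpha*w_j*(2*lambda - lambda_prev); after convergence on the
// working set the full KKT conditions are checked over every penalized
// coordinate and violators are added back, so screening never changes the
// solution.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

struct Workspace {
  int n, p;
  const double *X;          // column-major n x p
  std::vector<double> w;    // IRLS weights
  std::vector<double> res;  // working residual z - beta0 - X beta
  std::vector<double> xwx;  // (1/N) sum_i w_i x_ij^2 per column
  std::vector<double> mbeta; // M beta (only when fused)
};

// One pass of coordinate updates over the given index set (intercept first).
// Returns max absolute coefficient change.
static double cd_sweep(Workspace &ws,
                       const std::vector<int> &idx,
                       double &beta0, std::vector<double> &beta,
                       double alpha, double lambda1,
                       const double *l1w, double lambda2,
                       const double *M, bool fused) {
  const int n = ws.n, p = ws.p;
  double maxdel = 0.0;

  double sw = 0.0, swr = 0.0;
  for (int i = 0; i < n; ++i) { sw += ws.w[i]; swr += ws.w[i] * ws.res[i]; }
  double d0 = swr / sw;
  if (d0 != 0.0) {
    beta0 += d0;
    for (int i = 0; i < n; ++i) ws.res[i] -= d0;
    maxdel = std::fabs(d0);
  }

  for (size_t k = 0; k < idx.size(); ++k) {
    int j = idx[k];
    const double *xj = ws.X + (size_t)j * n;
    double bj = beta[j];
    double grad = 0.0;
    for (int i = 0; i < n; ++i) grad += ws.w[i] * xj[i] * ws.res[i];
    grad = grad / n + ws.xwx[j] * bj;
    double denom = ws.xwx[j] + lambda1 * (1.0 - alpha) * l1w[j];
    if (fused) {
      double cross = ws.mbeta[j] - M[(size_t)j * p + j] * bj;
      grad -= 2.0 * lambda2 * cross;
      denom += 2.0 * lambda2 * M[(size_t)j * p + j];
    }
    double bnew = soft(grad, lambda1 * alpha * l1w[j]) / denom;
    double del = bnew - bj;
    if (del != 0.0) {
      beta[j] = bnew;
      for (int i = 0; i < n; ++i) ws.res[i] -= xj[i] * del;
      if (fused) {
        const double *mj = M + (size_t)j * p;
        for (int q = 0; q < p; ++q) ws.mbeta[q] += mj[q] * del;
      }
      if (std::fabs(del) > maxdel) maxdel = std::fabs(del);
    }
  }
  return maxdel;
}

// Cycle the active subset using precomputed Gram columns (covariance
// updates): each coordinate update costs O(a) instead of O(n). Residuals are
// left stale on purpose and reconciled by the caller; the confirming naive
// sweep and the full KKT scan afterwards guarantee the solution is unchanged.
// Returns the number of sweeps performed.
static int gram_cycle(Workspace &ws,
                      const std::vector<int> &act,
                      double &beta0, std::vector<double> &beta,
                      double alpha, double lambda1,
                      const double *l1w, double lambda2,
                      const double *M, bool fused,
                      double tol, int max_sweeps) {
  const int n = ws.n, p = ws.p;
  const int a = (int)act.size();
  if (a == 0 || max_sweeps <= 0) return 0;

  // G[k*a+m] = (1/n) sum_i w_i x_{act[k]} x_{act[m]} (symmetric),
  // q[k] = (1/n) sum_i w_i x_{act[k]} res_i, swx[k] = sum_i w_i x_{act[k]},
  // q0 = sum_i w_i res_i, sw = sum_i w_i.
  // G is built as B'B via BLAS on B = diag(sqrt w) X_act.
  std::vector<double> G((size_t)a * a), q(a), swx(a);
  std::vector<double> B((size_t)n * a), sqw(n), u(n);
  double q0 = 0.0, sw = 0.0;
  for (int i = 0; i < n; ++i) {
    sw += ws.w[i];
    q0 += ws.w[i] * ws.res[i];
    sqw[i] = std::sqrt(ws.w[i]);
    u[i] = sqw[i] * ws.res[i];
  }
  for (int k = 0; k < a; ++k) {
    const double *xk = ws.X + (size_t)act[k] * n;
    double *bk = B.data() + (size_t)k * n;
    for (int i = 0; i < n; ++i) bk[i] = sqw[i] * xk[i];
  }
  {
    const char uplo = 'U', transT = 'T';
    const double invn = 1.0 / n, zero = 0.0;
    const int one_i = 1;
    F77_CALL(dsyrk)(&uplo, &transT, &a, &n, &invn, B.data(), &n,
                    &zero, G.data(), &a FCONE FCONE);
    for (int k = 0; k < a; ++k)
      for (int m = 0; m < k; ++m)
        G[(size_t)m * a + k] = G[(size_t)k * a + m];
    F77_CALL(dgemv)(&transT, &n, &a, &invn, B.data(), &n, u.data(), &one_i,
                    &zero, q.data(), &one_i FCONE);
    F77_CALL(dgemv)(&transT, &n, &a, &invn, B.data(), &n, sqw.data(), &one_i,
                    &zero, swx.data(), &one_i FCONE);
    for (int k = 0; k < a; ++k) swx[k] *= n;
  }

  int sweeps = 0;
  while (sweeps < max_sweeps) {
    double maxdel = 0.0;
    double d0 = q0 / sw;
    if (d0 != 0.0) {
      beta0 += d0;
      q0 -= d0 * sw;
      for (int m = 0; m < a; ++m) q[m] -= d0 * swx[m] / n;
      maxdel = std::fabs(d0);
    }
    for (int k = 0; k < a; ++k) {
      int j = act[k];
      double bj = beta[j];
      double grad = q[k] + G[(size_t)k * a + k] * bj;
      double denom = G[(size_t)k * a + k] + lambda1 * (1.0 - alpha) * l1w[j];
      if (fused) {
        double cross = ws.mbeta[j] - M[(size_t)j * p + j] * bj;
        grad -= 2.0 * lambda2 * cross;
        denom += 2.0 * lambda2 * M[(size_t)j * p + j];
      }
      double bnew = soft(grad, lambda1 * alpha * l1w[j]) / denom;
      double del = bnew - bj;
      if (del != 0.0) {
        beta[j] = bnew;
        const double *gk = G.data() + (size_t)k * a;
        for (int m = 0; m < a; ++m) q[m] -= gk[m] * del;
        q0 -= del * swx[k];
        if (fused) {
          const double *mj = M + (size_t)j * p;
          for (int z = 0; z < p; ++z) ws.mbeta[z] += mj[z] * del;
        }
        if (std::fabs(del) > maxdel) maxdel = std::fabs(del);
      }
    }
    ++sweeps;
    if (maxdel < tol) break;
  }
  return sweeps;
}

// Logistic gradient (1/N) X'(p - y) (+ fusion term) at the current iterate.
static void full_gradient(const NumericMatrix &X, const NumericVector &y,
                          double beta0, const std::vector<double> &beta,
                          double lambda2, const double *M, bool fused,
                          std::vector<double> &g) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = beta0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] == 0.0) continue;
    const double *xj = X.begin() + (size_t)j * n;
    for (int i = 0; i < n; ++i) resid[i] += xj[i] * beta[j];
  }
  for (int i = 0; i < n; ++i) {
    double e = resid[i];
    if (e > 35.0) e = 35.0; else if (e < -35.0) e = -35.0;
    resid[i] = 1.0 / (1.0 + std::exp(-e)) - y[i];
  }
  for (int j = 0; j < p; ++j) {
    const double *xj = X.begin() + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * resid[i];
    g[j] = s / n;
  }
  if (fused) {
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      const double *mj = M + (size_t)j * p;
      for (int q = 0; q < p; ++q) s += mj[q] * beta[q];
      g[j] += 2.0 * lambda2 * s;
    }
  }
}

// IRLS + CD to convergence on a fixed working set of coordinates.
static int irls_on_set(const NumericMatrix &X, const NumericVector &y,
                       double alpha, double lambda1, const NumericVector &l1w,
                       double lambda2, const double *M, bool fused,
                       double &beta0, std::vector<double> &beta,
                       const std::vector<int> &work,
                       int max_outer, int max_inner, double tol,
                       Workspace &ws) {
  const int n = X.nrow();
  std::vector<int> act;
  std::vector<double> eta(n);
  for (int outer = 0; outer < max_outer; ++outer) {
    bool used_gram = false;
    for (int i = 0; i < n; ++i) eta[i] = beta0;
    for (size_t k = 0; k < work.size(); ++k) {
      int j = work[k];
      if (beta[j] == 0.0) continue;
      const double *xj = X.begin() + (size_t)j * n;
      for (int i = 0; i < n; ++i) eta[i] += xj[i] * beta[j];
    }
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      if (e > 35.0) e = 35.0; else if (e < -35.0) e = -35.0;
      double pr = 1.0 / (1.0 + std::exp(-e));
      double wi = pr * (1.0 - pr);
      if (wi < 1e-5) wi = 1e-5;
      ws.w[i] = wi;
      ws.res[i] = (y[i] - pr) / wi;
    }
    for (size_t k = 0; k < work.size(); ++k) {
      int j = work[k];
      const double *xj = X.begin() + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += ws.w[i] * xj[i] * xj[i];
      ws.xwx[j] = s / n;
    }

    // inner CD: full working-set sweep, then cycle its active subset (naive
    // at first, switching to Gram/covariance updates once the naive sweeps
    // exceed the Gram build cost), then confirm with a working-set sweep
    double out_max = cd_sweep(ws, work, beta0, beta, alpha, lambda1,
                              l1w.begin(), lambda2, M, fused);
    int inner = 1;
    while (inner < max_inner) {
      act.clear();
      for (size_t k = 0; k < work.size(); ++k)
        if (beta[work[k]] != 0.0) act.push_back(work[k]);
      double da;
      int naive_left = used_gram ? 1 : 2;
      do {
        da = cd_sweep(ws, act, beta0, beta, alpha, lambda1,
                      l1w.begin(), lambda2, M, fused);
        if (da > out_max) out_max = da;
        ++inner;
        --naive_left;
      } while (da >= tol && naive_left > 0 && inner < max_inner);
      if (da >= tol && inner < max_inner) {
        used_gram = true;
        double b0_old = beta0;
        std::vector<double> b_old(act.size());
        for (size_t k = 0; k < act.size(); ++k) b_old[k] = beta[act[k]];
        int done = gram_cycle(ws, act, beta0, beta, alpha, lambda1,
                              l1w.begin(), lambda2, M, fused,
                              tol, max_inner - inner);
        inner += done;
        // reconcile the stale residuals with the net coefficient change
        double d0 = beta0 - b0_old;
        if (d0 != 0.0) for (int i = 0; i < n; ++i) ws.res[i] -= d0;
        for (size_t k = 0; k < act.size(); ++k) {
          double del = beta[act[k]] - b_old[k];
          if (del == 0.0) continue;
          const double *xj = X.begin() + (size_t)act[k] * n;
          for (int i = 0; i < n; ++i) ws.res[i] -= xj[i] * del;
        }
      }
        double df = cd_sweep(ws, work, beta0, beta, alpha, lambda1,
                           l1w.begin(), lambda2, M, fused);
      if (df > out_max) out_max = df;
      ++inner;
      if (df < tol) break;
    }
    if (out_max < tol) return outer + 1;
  }
  return -1;
}

// Fit at a single penalty point from a warm start. lambda_prev < 0 disables
// strong-rule screening (the working set starts as all penalized coords).
static int cd_fit_one(const NumericMatrix &X, const NumericVector &y,
                      double alpha, double lambda1, const NumericVector &l1w,
                      double lambda2, const double *M, bool fused,
                      double &beta0, std::vector<double> &beta,
                      int max_outer, int max_inner, double tol,
                      double lambda_prev,
                      std::vector<double> &g, bool &g_valid) {
  const int n = X.nrow(), p = X.ncol();
  Workspace ws;
  ws.n = n; ws.p = p; ws.X = X.begin();
  ws.w.assign(n, 0.0); ws.res.assign(n, 0.0); ws.xwx.assign(p, 0.0);

  std::vector<char> penal(p, 0), inset(p, 0);
  for (int j = 0; j < p; ++j) {
    if (R_finite(l1w[j])) penal[j] = 1;
    else beta[j] = 0.0;
  }

  std::vector<int> work;
  if (lambda_prev >= 0.0) {
    // the gradient does not depend on the penalty, so the previous fit's
    // final KKT gradient (taken at this warm start) can be reused
    if (!g_valid) full_gradient(X, y, beta0, beta, lambda2, M, fused, g);
    g_valid = false;
    double fac = 2.0 * lambda1 - lambda_prev;
    for (int j = 0; j < p; ++j) {
      if (!penal[j]) continue;
      if (beta[j] != 0.0 || std::fabs(g[j]) > alpha * l1w[j] * fac) {
        work.push_back(j);
        inset[j] = 1;
      }
    }
  } else {
    g_valid = false;
    for (int j = 0; j < p; ++j)
      if (penal[j]) { work.push_back(j); inset[j] = 1; }
  }

  if (fused) {
    ws.mbeta.assign(p, 0.0);
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0)
        for (int q = 0; q < p; ++q) ws.mbeta[q] += M[(size_t)j * p + q] * beta[j];
  }

  int iters = 0;
  for (int round = 0; round < p + 1; ++round) {
    int it = irls_on_set(X, y, alpha, lambda1, l1w, lambda2, M, fused,
                         beta0, beta, work, max_outer, max_inner, tol, ws);
    if (it < 0) return -1;
    iters += it;
    // exact KKT check over all penalized coordinates
    full_gradient(X, y, beta0, beta, lambda2, M, fused, g);
    bool violated = false;
    for (int j = 0; j < p; ++j) {
      if (!penal[j] || inset[j]) continue;
      if (std::fabs(g[j]) > lambda1 * alpha * l1w[j] + 1e-9) {
        work.push_back(j);
        inset[j] = 1;
        violated = true;
      }
    }
    if (!violated) { g_valid = true; return iters; }
  }
  return -1;
}

// [[Rcpp::export]]
List cpp_cd_fit(NumericMatrix X, NumericVector y,
                double alpha, double lambda1, NumericVector l1w,
                double lambda2, Nullable<NumericMatrix> M_,
                double beta0_init, NumericVector beta_init,
                int max_outer, int max_inner, double tol) {
  bool fused = false;
  const double *M = nullptr;
  NumericMatrix Mm;
  if (M_.isNotNull() && lambda2 > 0.0) {
    Mm = NumericMatrix(M_);
    M = Mm.begin();
    fused = true;
  }
  double beta0 = beta0_init;
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> g(X.ncol());
  bool g_valid = false;
  int it = cd_fit_one(X, y, alpha, lambda1, l1w, lambda2, M, fused,
                      beta0, beta, max_outer, max_inner, tol, -1.0,
                      g, g_valid);
  return List::create(_["beta0"] = beta0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = it > 0,
                      _["iterations"] = it > 0 ? it : max_outer);
}

// Warm-started path over a decreasing lambda1 sequence at fixed
// (alpha, l1w, lambda2, M). Returns (p+1) x nlambda coefficients.
// [[Rcpp::export]]
List cpp_cd_path(NumericMatrix X, NumericVector y,
                 double alpha, NumericVector lambdas, NumericVector l1w,
                 double lambda2, Nullable<NumericMatrix> M_,
                 int max_outer, int max_inner, double tol) {
  const int p = X.ncol(), nl = lambdas.size();
  bool fused = false;
  const double *M = nullptr;
  NumericMatrix Mm;
  if (M_.isNotNull() && lambda2 > 0.0) {
    Mm = NumericMatrix(M_);
    M = Mm.begin();
    fused = true;
  }
  const int n = X.nrow();
  NumericMatrix coefs(p + 1, nl);
  LogicalVector conv(nl);
  double beta0 = 0.0;
  std::vector<double> beta(p, 0.0);
  std::vector<double> eta(n);
  std::vector<double> g(p);
  bool g_valid = false;
  double null_dev = -1.0;
  int stop_at = nl;
  for (int l = 0; l < nl; ++l) {
    double lprev = l > 0 ? lambdas[l - 1] : lambdas[l];
    int it = cd_fit_one(X, y, alpha, lambdas[l], l1w, lambda2, M, fused,
                        beta0, beta, max_outer, max_inner, tol, lprev,
                        g, g_valid);
    conv[l] = it > 0;
    coefs(0, l) = beta0;
    for (int j = 0; j < p; ++j) coefs(j + 1, l) = beta[j];
    // training deviance; stop the path once the fit is near-saturated
    // (almost-separable data at small lambda otherwise dominates runtime)
    for (int i = 0; i < n; ++i) eta[i] = beta0;
    for (int j = 0; j < p; ++j) {
      if (beta[j] == 0.0) continue;
      const double *xj = X.begin() + (size_t)j * n;
      for (int i = 0; i < n; ++i) eta[i] += xj[i] * beta[j];
    }
    double dev = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      double lse = (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e)));
      dev += -2.0 * (y[i] * e - lse);
    }
    if (null_dev < 0) null_dev = dev;
    if (l > 0 && dev < 0.001 * null_dev) { stop_at = l + 1; break; }
  }
  // carry the last solution forward so every lambda has coefficients; ties
  // in downstream CV resolve toward the larger lambda
  for (int l = stop_at; l < nl; ++l) {
    conv[l] = conv[stop_at - 1];
    for (int j = 0; j <= p; ++j) coefs(j, l) = coefs(j, stop_at - 1);
  }
  return List::create(_["coefs"] = coefs, _["converged"] = conv,
                      _["stopped_at"] = stop_at);
}
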