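#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// SMO (maximal-violating-pair) solver for the instance-weighted
// epsilon-SVR dual:
//
//   max  sum_i y_i beta_i - 1/2 sum_ij beta_i beta_j K_ij
//        - eps * sum_i (alpha_i + alpha*_i)
//   s.t. sum_i beta_i = 0,  beta_i = alpha_i - alpha*_i,
//        alpha_i, alpha*_i in [0, U_i],  U_i = C * Omega_i.
//
// Internally the 2L-variable form is used: a = (alpha, alpha*) with
// z = (+1,...,+1, -1,...,-1), minimizing
//   f(a) = 1/2 a' Q a + p' a,  Q_st = z_s z_t K_(s mod L)(t mod L),
//   p = (eps - y, eps + y),  s.t. z'a = 0, 0 <= a_t <= U_(t mod L).
//
// Stops when the maximal KKT violation m(a) - M(a) <= tol.
// [[Rcpp::export(name = ".smo_svr")]]
List smo_svr(NumericMatrix K, NumericVector y, NumericVector U,
             double eps, double tol = 1e-8, int max_iter = 1000000) {
  const int L = y.size();
  const int n = 2 * L;
  std::vector<double> a(n, 0.0), grad(n), z(n), ub(n);
  for (int t = 0; t < n; ++t) {
    int i = t % L;
    z[t] = (t < L) ? 1.0 : -1.0;
    ub[t] = U[i];
    grad[t] = (t < L) ? (eps - y[i]) : (eps + y[i]);
  }

  auto Qst = [&](int s, int t) -> double {
    return z[s] * z[t] * K(s % L, t % L);
  };

  int iter = 0;
  double gap = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    // first index: maximal violation on the "up" side
    int i = -1;
    double m = -R_PosInf, M = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = -z[t] * grad[t];
      bool up = (z[t] > 0) ? (a[t] < ub[t] - 1e-14) : (a[t] > 1e-14);
      bool lo = (z[t] > 0) ? (a[t] > 1e-14) : (a[t] < ub[t] - 1e-14);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) M = v;
    }
    gap = m - M;
    if (i < 0 || !std::isfinite(M) || gap <= tol) break;

    // second index: maximal second-order objective decrease among the
    // sufficiently violating "low" candidates (LIBSVM-style selection)
    int j = -1;
    double best_gain = -R_PosInf;
    double Qii = Qst(i, i);
    for (int t = 0; t < n; ++t) {
      bool lo = (z[t] > 0) ? (a[t] > 1e-14) : (a[t] < ub[t] - 1e-14);
      if (!lo) continue;
      double v = -z[t] * grad[t];
      double diff = m - v;
      if (diff <= tol) continue;
      double eta = Qii + Qst(t, t) - 2.0 * z[i] * z[t] * Qst(i, t);
      if (eta <= 1e-12) eta = 1e-12;
      double gain = diff * diff / eta;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) break;

    // analytic two-variable step along the feasible direction
    // d_i = +z_i * t, d_j = -z_j * t  (keeps z'a constant)
    double vj = -z[j] * grad[j];
    double eta = Qii + Qst(j, j) - 2.0 * z[i] * z[j] * Qst(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    double step = (m - vj) / eta; // unconstrained minimizer along direction

    // box clipping
    double max_i = (z[i] > 0) ? (ub[i] - a[i]) : a[i];
    double max_j = (z[j] > 0) ? a[j] : (ub[j] - a[j]);
    if (step > max_i) step = max_i;
    if (step > max_j) step = max_j;

    double di = z[i] * step, dj = -z[j] * step;
    a[i] += di;
    a[j] += dj;

    for (int t = 0; t < n; ++t) {
      grad[t] += Qst(t, i) * di + Qst(t, j) * dj;
    }
  }

  // recover beta, bias from the optimality interval
  NumericVector beta(L);
  for (int i2 = 0; i2 < L; ++i2) beta[i2] = a[i2] - a[i2 + L];
  double m = -R_PosInf, M = R_PosInf;
  for (int t = 0; t < n; ++t) {
    double v = -z[t] * grad[t];
    bool up = (z[t] > 0) ? (a[t] < ub[t] - 1e-14) : (a[t] > 1e-14);
    bool lo = (z[t] > 0) ? (a[t] > 1e-14) : (a[t] < ub[t] - 1e-14);
    if (up && v > m) m = v;
    if (lo && v < M) M = v;
  }
  double b;
  if (std::isfinite(m) && std::isfinite(M)) b = 0.5 * (m + M);
  else if (std::isfinite(m)) b = m;
  else if (std::isfinite(M)) b = M;
  else b = 0.0;

  return List::create(_["beta"] = beta, _["b"] = b,
                      _["iterations"] = iter, _["kkt_gap"] = gap,
                      _["converged"] = (gap <= tol));
}
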