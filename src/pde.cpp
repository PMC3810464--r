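#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit-Euler / 3-point-stencil integrator for the two-sex
// reaction-diffusion system
//   df/dt = D_f f_xx + sigma r     f m (1 - f - m) - mu_f f
//   dm/dt = D_m m_xx + sigma (1-r) f m (1 - f - m) - mu_m m
// on a uniform 1-D grid. boundary: 0 = no-flux (zero-gradient ghost),
// 1 = absorbing (zero ghost).
//
// Status codes: 0 converged (max |du/dt| < tol), 1 hit max_time,
// 2 certified early extinction (all f < f_exit and all m < m_exit),
// 3 non-finite values encountered,
// 4 certified early persistence (all f > f_pers and all m > m_pers:
//   the state dominates a homogeneous state inside the restoration basin).

static inline double lap(const std::vector<double>& u, int i, int n,
                         double inv_dx2, int boundary) {
  double left  = (i > 0)     ? u[i - 1] : (boundary == 0 ? u[0]     : 0.0);
  double right = (i < n - 1) ? u[i + 1] : (boundary == 0 ? u[n - 1] : 0.0);
  return (left - 2.0 * u[i] + right) * inv_dx2;
}

// [[Rcpp::export]]
List pde_run_cpp(NumericVector f0, NumericVector m0,
                 double r, double mu_f, double mu_m,
                 double D_f, double D_m, double sigma,
                 double dx, double dt, int boundary,
                 double tol, double max_time, double t0,
                 double record_every,
                 double f_exit, double m_exit,
                 double f_pers, double m_pers,
                 long long n_steps) {
  const int n = f0.size();
  std::vector<double> f(f0.begin(), f0.end()), m(m0.begin(), m0.end());
  std::vector<double> df(n), dm(n);
  const double inv_dx2 = 1.0 / (dx * dx);

  std::vector<double> rec_t;
  std::vector< std::vector<double> > rec_f, rec_m;
  double next_rec = record_every > 0 ? t0 : R_PosInf;

  double t = t0;
  long long step = 0, max_steps = n_steps > 0
    ? n_steps
    : (long long)std::ceil((max_time - t0) / dt) + 2;
  int status = 1;
  double maxderiv = R_PosInf;

  while (step < max_steps && (n_steps > 0 || t < max_time - 1e-12)) {
    if (record_every > 0 && t >= next_rec - 1e-9) {
      rec_t.push_back(t);
      rec_f.push_back(f);
      rec_m.push_back(m);
      next_rec += record_every;
    }
    maxderiv = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 1.0 - f[i] - m[i];
      double growth_f = sigma * r * f[i] * m[i] * s;
      double growth_m = sigma * (1.0 - r) * f[i] * m[i] * s;
      double rf = D_f * lap(f, i, n, inv_dx2, boundary) + growth_f - mu_f * f[i];
      double rm = D_m * lap(m, i, n, inv_dx2, boundary) + growth_m - mu_m * m[i];
      df[i] = rf;
      dm[i] = rm;
      double a = std::fabs(rf), b = std::fabs(rm);
      if (a > maxderiv) maxderiv = a;
      if (b > maxderiv) maxderiv = b;
    }
    if (!R_FINITE(maxderiv)) { status = 3; break; }
    double maxf = 0.0, maxm = 0.0, minf = R_PosInf, minm = R_PosInf;
    for (int i = 0; i < n; ++i) {
      f[i] += dt * df[i];
      m[i] += dt * dm[i];
      if (f[i] < 0.0) f[i] = 0.0;
      if (m[i] < 0.0) m[i] = 0.0;
      if (f[i] > maxf) maxf = f[i];
      if (m[i] > maxm) maxm = m[i];
      if (f[i] < minf) minf = f[i];
      if (m[i] < minm) minm = m[i];
    }
    t += dt;
    ++step;
    if (n_steps <= 0) {
      if (maxderiv < tol) { status = 0; break; }
      if (f_exit > 0 && maxf < f_exit && maxm < m_exit) { status = 2; break; }
      if (f_pers > 0 && minf > f_pers && minm > m_pers) { status = 4; break; }
    }
  }
  if (n_steps > 0) status = 0;
  if (record_every > 0 && status != 3) {  // final state snapshot
    rec_t.push_back(t);
    rec_f.push_back(f);
    rec_m.push_back(m);
  }

  List rec = R_NilValue;
  if (record_every > 0) {
    int k = rec_t.size();
    NumericVector rt(k);
    NumericMatrix rf(k, n), rm(k, n);
    for (int j = 0; j < k; ++j) {
      rt[j] = rec_t[j];
      for (int i = 0; i < n; ++i) { rf(j, i) = rec_f[j][i]; rm(j, i) = rec_m[j][i]; }
    }
    rec = List::create(_["time"] = rt, _["f"] = rf, _["m"] = rm);
  }
  return List::create(
    _["f"] = NumericVector(f.begin(), f.end()),
    _["m"] = NumericVector(m.begin(), m.end()),
    _["time"] = t, _["steps"] = (double)step,
    _["status"] = status, _["max_deriv"] = maxderiv,
    _["records"] = rec);
}

// Reduced single-sex equation du/dt = D u_xx + sigma/2 u^2 (1 - 2u) - mu u.
// The reaction term is written with exactly the same floating-point
// operation order as the two-sex kernel at r = 1/2, f = m = u, so the
// symmetric reduction is exact to the bit.

// [[Rcpp::export]]
List pde_run_single_cpp(NumericVector u0, double mu, double D, double sigma,
                        double dx, double dt, int boundary,
                        double tol, double max_time, double t0,
                        double record_every, double u_exit, double u_pers,
                        long long n_steps) {
  const int n = u0.size();
  std::vector<double> u(u0.begin(), u0.end()), du(n);
  const double inv_dx2 = 1.0 / (dx * dx);

  std::vector<double> rec_t;
  std::vector< std::vector<double> > rec_u;
  double next_rec = record_every > 0 ? t0 : R_PosInf;

  double t = t0;
  long long step = 0, max_steps = n_steps > 0
    ? n_steps
    : (long long)std::ceil((max_time - t0) / dt) + 2;
  int status = 1;
  double maxderiv = R_PosInf;

  while (step < max_steps && (n_steps > 0 || t < max_time - 1e-12)) {
    if (record_every > 0 && t >= next_rec - 1e-9) {
      rec_t.push_back(t);
      rec_u.push_back(u);
      next_rec += record_every;
    }
    maxderiv = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 1.0 - u[i] - u[i];
      double growth = sigma * 0.5 * u[i] * u[i] * s;
      double ru = D * lap(u, i, n, inv_dx2, boundary) + growth - mu * u[i];
      du[i] = ru;
      double a = std::fabs(ru);
      if (a > maxderiv) maxderiv = a;
    }
    if (!R_FINITE(maxderiv)) { status = 3; break; }
    double maxu = 0.0, minu = R_PosInf;
    for (int i = 0; i < n; ++i) {
      u[i] += dt * du[i];
      if (u[i] < 0.0) u[i] = 0.0;
      if (u[i] > maxu) maxu = u[i];
      if (u[i] < minu) minu = u[i];
    }
    t += dt;
    ++step;
    if (n_steps <= 0) {
      if (maxderiv < tol) { status = 0; break; }
      if (u_exit > 0 && maxu < u_exit) { status = 2; break; }
      if (u_pers > 0 && minu > u_pers) { status = 4; break; }
    }
  }
  if (n_steps > 0) status = 0;
  if (record_every > 0 && status != 3) {
    rec_t.push_back(t);
    rec_u.push_back(u);
  }

  List rec = R_NilValue;
  if (record_every > 0) {
    int k = rec_t.size();
    NumericVector rt(k);
    NumericMatrix ru(k, n);
    for (int j = 0; j < k; ++j) {
      rt[j] = rec_t[j];
      for (int i = 0; i < n; ++i) ru(j, i) = rec_u[j][i];
    }
    rec = List::create(_["time"] = rt, _["u"] = ru);
  }
  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["time"] = t, _["steps"] = (double)step,
    _["status"] = status, _["max_deriv"] = maxderiv,
    _["records"] = rec);
}
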