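// Stage-structured consumer-resource spheroid model.
//
// State vector (7): P_S, Z_S, X_S, P_R, Z_R, X_R, E_E
//   P = proliferative, Z = quiescent, X = senescent cells; E_E = extracellular
//   facilitation-factor (estradiol) concentration.
//
// Parameter vector layout (fixed order, shared with R/mechanistic.R):
//   0  r_S      1  r_R       baseline G1/S entry rate (1/day)
//   2  lambda_S 3  lambda_R  baseline quiescence rate (1/day)
//   4  phi_S    5  phi_R     quiescent -> senescent rate (1/day)
//   6  delta_S  7  delta_R   senescent death rate (1/day)
//   8  k_S      9  k_R       ribociclib half-max dose (nM)
//   10 K_S      11 K_R       competitive carrying capacity (cells)
//   12 gamma_S  13 gamma_R   net estradiol secretion per cell (conc/day)
//   14 rho_S    15 rho_R     intracellular production rate
//   16 mu_S     17 mu_R      receptor binding rate
//   18 eta                    cell <-> medium diffusion rate
//   19 c                      facilitation saturation constant
//   20 sigma_E                external influx (enters only the fast subsystem)
//   21 delta_E                extracellular decay (1/day)
//   22 nu       23 k_nu       plasticity switching rate / half-max dose
//
// Variant codes: 1 facilitation, 2 competition_only,
//                3 plasticity_induced, 4 plasticity_random.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 7;

struct Pars {
  double r[2], lam[2], phi[2], del[2], k[2], K[2], gam[2], rho[2], mu[2];
  double eta, c, sigmaE, delE, nu, knu;
  int variant;
  double dose;
};

static Pars make_pars(const double* th, int variant, double dose) {
  Pars p;
  for (int i = 0; i < 2; ++i) {
    p.r[i]   = th[0 + i];  p.lam[i] = th[2 + i];
    p.phi[i] = th[4 + i];  p.del[i] = th[6 + i];
    p.k[i]   = th[8 + i];  p.K[i]   = th[10 + i];
    p.gam[i] = th[12 + i]; p.rho[i] = th[14 + i];
    p.mu[i]  = th[16 + i];
  }
  p.eta = th[18]; p.c = th[19]; p.sigmaE = th[20]; p.delE = th[21];
  p.nu = th[22]; p.knu = th[23];
  p.variant = variant; p.dose = dose;
  return p;
}

static inline void rhs(const double* y, double* dy, const Pars& p) {
  const double EE = y[6];
  const double NS = y[0] + y[1] + y[2];
  const double NR = y[3] + y[4] + y[5];
  double alpha = 1.0 - NS / p.K[0] - NR / p.K[1];
  if (alpha < 0.0) alpha = 0.0;  // checkpoint entry cannot be negative
  const bool facil = (p.variant == 1);
  double G[2], q[2];
  for (int i = 0; i < 2; ++i) {
    double fac = 0.0;
    if (facil) {
      const double Ei = (p.rho[i] + p.eta * EE) / (p.eta + p.mu[i]);
      const double me = p.mu[i] * Ei;
      fac = me / (1.0 + p.c * me);
    }
    G[i] = p.r[i] * (1.0 + fac) * alpha;
    q[i] = p.dose / (p.k[i] + p.dose);
  }
  for (int i = 0; i < 2; ++i) {
    const double P = y[3 * i], Z = y[3 * i + 1], X = y[3 * i + 2];
    dy[3 * i]     = (G[i] * (1.0 - 2.0 * q[i]) - p.lam[i]) * P;
    dy[3 * i + 1] = (G[i] * q[i] + p.lam[i]) * P - p.phi[i] * Z;
    dy[3 * i + 2] = p.phi[i] * Z - p.del[i] * X;
  }
  if (facil)
    dy[6] = p.gam[0] * (y[0] + y[1]) + p.gam[1] * (y[3] + y[4]) - p.delE * EE;
  else
    dy[6] = -p.delE * EE;
  if (p.variant == 3 || p.variant == 4) {
    // sensitive (naive) -> resistant switching, drug-induced or random
    const double rate = (p.variant == 4)
      ? p.nu : p.nu * p.dose / (p.knu + p.dose);
    const double flux = rate * y[0];
    dy[0] -= flux; dy[3] += flux;
  }
}

// Dormand-Prince 5(4) adaptive step integrator.
// Returns 0 on success; fills `out` (ntimes x NSTATE, row-major by time).
static int integrate_dp45(const Pars& p, const double* y0, double t0,
                          const double* times, int ntimes, double* out,
                          double rtol, double atol, int* nclip) {
  // (stage times c2..c5 are implicit in the autonomous RHS)

  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;

  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
         k5[NSTATE], k6[NSTATE], k7[NSTATE], ytmp[NSTATE], ynew[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];
  double t = t0;
  *nclip = 0;

  int it = 0;
  while (it < ntimes && times[it] <= t0 + 1e-12) {
    for (int i = 0; i < NSTATE; ++i) out[it * NSTATE + i] = y[i];
    ++it;
  }
  if (it >= ntimes) return 0;

  double h = 0.05;
  rhs(y, k1, p);
  long nstep = 0;
  const long maxstep = 200000;

  while (it < ntimes) {
    const double tend = times[it];
    if (t + h > tend) h = tend - t;
    if (h < 1e-14) h = 1e-14;

    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(ytmp, k2, p);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(ytmp, k3, p);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(ytmp, k4, p);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(ytmp, k5, p);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(ytmp, k6, p);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(ynew, k7, p);

    double err = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      const double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / NSTATE);

    if (!std::isfinite(err)) return 1;
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) {
        y[i] = ynew[i];
        if (y[i] < 0.0) { y[i] = 0.0; ++(*nclip); }
        k1[i] = k7[i];  // FSAL
      }
      if (*nclip > 0) rhs(y, k1, p);
      while (it < ntimes && times[it] <= t + 1e-10) {
        for (int i = 0; i < NSTATE; ++i) out[it * NSTATE + i] = y[i];
        ++it;
      }
    }
    double fac = 0.9 * std::pow(err > 1e-12 ? 1.0 / err : 1e12, 0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h > 2.0) h = 2.0;
    if (++nstep > maxstep) return 2;
  }
  return 0;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector params, int variant,
                           NumericVector init, double dose,
                           double t0, NumericVector times,
                           double rtol, double atol) {
  if (params.size() < 24) stop("parameter vector must have 24 entries");
  if (init.size() != NSTATE) stop("init must have 7 entries");
  Pars p = make_pars(params.begin(), variant, dose);
  const int nt = times.size();
  std::vector<double> out(nt * NSTATE);
  int nclip = 0;
  int code = integrate_dp45(p, init.begin(), t0, times.begin(), nt,
                            out.data(), rtol, atol, &nclip);
  if (code != 0)
    stop("ODE integration failed (code %d) at dose %.1f", code, dose);
  NumericMatrix res(nt, NSTATE);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < NSTATE; ++j) res(i, j) = out[i * NSTATE + j];
  res.attr("n_clipped") = nclip;
  return res;
}

// Shared worker: per-observation lognormal log-likelihood of a dose panel.
// conds: ncond x 3 matrix (dose, S0, R0); observations reference conditions
// by 1-based index. Lineage: 0 = sensitive, 1 = resistant. Observable is
// P + Z + X of the lineage.
static double panel_loglik_one(const double* theta, int variant,
                               const NumericMatrix& conds,
                               const IntegerVector& obs_cond,
                               const NumericVector& obs_day,
                               const IntegerVector& obs_lineage,
                               const NumericVector& obs_count,
                               double rtol, double atol,
                               double* pointwise /* may be null */) {
  const int ncond = conds.nrow();
  const int nobs = obs_cond.size();
  const double sigma = theta[24];
  if (!(sigma > 0.0)) return -1e12;
  const double LOG2PI = 1.8378770664093453;

  // group observation days per condition
  std::vector<std::vector<double>> days(ncond);
  std::vector<std::vector<int>> oidx(ncond);
  for (int o = 0; o < nobs; ++o) {
    const int cnd = obs_cond[o] - 1;
    days[cnd].push_back(obs_day[o]);
    oidx[cnd].push_back(o);
  }

  double total = 0.0;
  for (int cnd = 0; cnd < ncond; ++cnd) {
    if (days[cnd].empty()) continue;
    // sorted unique days
    std::vector<double> ud = days[cnd];
    std::sort(ud.begin(), ud.end());
    ud.erase(std::unique(ud.begin(), ud.end(),
             [](double a, double b) { return std::fabs(a - b) < 1e-9; }),
             ud.end());
    Pars p = make_pars(theta, variant, conds(cnd, 0));
    double y0[NSTATE] = {conds(cnd, 1), 0, 0, conds(cnd, 2), 0, 0, 0};
    std::vector<double> out(ud.size() * NSTATE);
    int nclip = 0;
    int code = integrate_dp45(p, y0, 0.0, ud.data(), (int)ud.size(),
                              out.data(), rtol, atol, &nclip);
    if (code != 0) return -1e12;
    for (size_t j = 0; j < oidx[cnd].size(); ++j) {
      const int o = oidx[cnd][j];
      size_t ti = 0;
      while (ti < ud.size() && std::fabs(ud[ti] - obs_day[o]) > 1e-9) ++ti;
      const double* st = &out[ti * NSTATE];
      const int L = obs_lineage[o];
      const double pred = st[3 * L] + st[3 * L + 1] + st[3 * L + 2];
      double ll;
      if (pred <= 0.0 || obs_count[o] <= 0.0) {
        ll = -1e10;
      } else {
        const double z = (std::log(obs_count[o]) - std::log(pred)) / sigma;
        ll = -0.5 * z * z - std::log(sigma) - 0.5 * LOG2PI -
             std::log(obs_count[o]);
      }
      if (pointwise) pointwise[o] = ll;
      total += ll;
    }
  }
  return total;
}

// [[Rcpp::export]]
List cpp_panel_loglik(NumericVector theta, int variant, NumericMatrix conds,
                      IntegerVector obs_cond, NumericVector obs_day,
                      IntegerVector obs_lineage, NumericVector obs_count,
                      double rtol, double atol) {
  if (theta.size() < 25) stop("theta must have 25 entries (24 params + sigma)");
  NumericVector pw(obs_cond.size());
  double total = panel_loglik_one(theta.begin(), variant, conds, obs_cond,
                                  obs_day, obs_lineage, obs_count, rtol,
                                  atol, pw.begin());
  return List::create(_["total"] = total, _["pointwise"] = pw);
}

// Batched evaluation over rows of a theta matrix (used for finite-difference
// gradients inside the HMC sampler).
// [[Rcpp::export]]
NumericVector cpp_panel_loglik_mat(NumericMatrix theta_mat, int variant,
                                   NumericMatrix conds,
                                   IntegerVector obs_cond,
                                   NumericVector obs_day,
                                   IntegerVector obs_lineage,
                                   NumericVector obs_count,
                                   double rtol, double atol) {
  const int m = theta_mat.nrow();
  if (theta_mat.ncol() < 25) stop("theta matrix must have 25 columns");
  NumericVector res(m);
  std::vector<double> th(theta_mat.ncol());
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < theta_mat.ncol(); ++j) th[j] = theta_mat(r, j);
    res[r] = panel_loglik_one(th.data(), variant, conds, obs_cond, obs_day,
                              obs_lineage, obs_count, rtol, atol, nullptr);
  }
  return res;
}
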