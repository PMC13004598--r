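// Core numerics: menstrual-cycle DDE right-hand side with circadian
// modulation and exogenous-hormone coupling, integrated by an adaptive
// Dormand-Prince 5(4) scheme using the method of steps (single constant
// inhibin delay, cubic-Hermite history interpolation), plus the closed-form
// tri-exponential two-compartment PK superposition evaluated inside the RHS.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const int NSTATE = 12;
// state order: RP_LH, LH, RP_FSH, FSH, RcF, GrF, DomF, Lut1..Lut4, Inh
enum {
  iRP_LH, iLH, iRP_FSH, iFSH, iRcF, iGrF, iDomF,
  iLut1, iLut2, iLut3, iLut4, iInh
};
// parameter vector order (kept in lockstep with R's .param_order)
enum {
  pV0_LH, pV1_LH, pKm_LH, pKi_LH_P, pk_LH, pc_LH_P, pc_LH_E, pa_LH,
  pV_FSH, pKi_FSH_Inh, pw, pk_FSH, pc_FSH_P, pc_FSH_E, pa_FSH, pv,
  pb, pc1, pc2, pc3, pc4, pd1, pd2, pk1, pk2, pk3, pk4,
  pAlphaExp, pBetaExp, pGammaExp, pNuExp, pe0, pe1, pe2, pe3, pp0, pp1, pp2,
  ph0, ph1, ph2, ph3, pk_Inh, ptau, pr1, pr2, NPAR
};

struct PkDrug {
  // per-unit-dose tri-exponential coefficients (concentration scale applied)
  std::vector<double> t_dose, amount;
  double ka, a1, b1, Nu, Lu, Mu;
  bool any;
  // concentration at time t (model days); doses older than `horizon` in the
  // slowest phase contribute < exp(-40) of scale and are skipped
  double conc(double t) const {
    if (!any) return 0.0;
    double horizon = 40.0 / b1;
    // first index with t_dose > t - horizon
    size_t lo = std::lower_bound(t_dose.begin(), t_dose.end(), t - horizon) -
                t_dose.begin();
    double c = 0.0;
    for (size_t i = lo; i < t_dose.size(); ++i) {
      double dt = t - t_dose[i];
      if (dt < 0) break;
      c += amount[i] * (Nu * std::exp(-ka * dt) + Lu * std::exp(-a1 * dt) +
                        Mu * std::exp(-b1 * dt));
    }
    return c < 0 ? 0.0 : c;
  }
};

static inline double cosfac(double t, double amp, double phase) {
  return 1.0 + amp * std::cos(2.0 * M_PI * (t - phase));
}

// full RHS; E2/P4 observables (with circadian factor on the endogenous part
// and RBA-scaled exogenous additions) feed back into every regulation term
static void rhs_core(double t, const double* y, double inh_lag,
                     const double* p, const double* amp, const double* phase,
                     double e2exo, double p4exo, double* dy) {
  double E2 = (p[pe0] + p[pe1] * y[iGrF] + p[pe2] * y[iDomF] +
               p[pe3] * y[iLut4]) * cosfac(t, amp[2], phase[2]) +
              p[pr1] * e2exo;
  double P4 = (p[pp0] + p[pp1] * y[iLut3] + p[pp2] * y[iLut4]) *
              cosfac(t, amp[3], phase[3]) + p[pr2] * p4exo;
  double E2c = E2 > 0 ? E2 : 0.0, P4c = P4 > 0 ? P4 : 0.0;
  double LH = y[iLH] > 0 ? y[iLH] : 0.0, FSH = y[iFSH];

  double hillE2 = std::pow(E2c, 8.0);
  double synthLH = (p[pV0_LH] + p[pV1_LH] * hillE2 /
                    (std::pow(p[pKm_LH], 8.0) + hillE2)) /
                   (1.0 + P4c / p[pKi_LH_P]) * cosfac(t, amp[0], phase[0]);
  double relLH = p[pk_LH] * (1.0 + p[pc_LH_P] * P4c) * y[iRP_LH] /
                 (1.0 + p[pc_LH_E] * E2c);
  double synthFSH = p[pV_FSH] /
                    (1.0 + inh_lag / p[pKi_FSH_Inh] + P4c / p[pw]) *
                    cosfac(t, amp[1], phase[1]);
  double relFSH = p[pk_FSH] * (1.0 + p[pc_FSH_P] * P4c) * y[iRP_FSH] /
                  (1.0 + p[pc_FSH_E] * E2c * E2c);

  double lh_a = std::pow(LH, p[pAlphaExp]);
  double ovul = p[pd2] * std::pow(LH, p[pNuExp]);

  dy[iRP_LH] = synthLH - relLH;
  dy[iLH] = relLH / p[pv] - p[pa_LH] * y[iLH];
  dy[iRP_FSH] = synthFSH - relFSH;
  dy[iFSH] = relFSH / p[pv] - p[pa_FSH] * y[iFSH];
  dy[iRcF] = p[pb] * FSH + (p[pc1] * FSH - p[pc2] * lh_a) * y[iRcF];
  dy[iGrF] = p[pc2] * lh_a * y[iRcF] +
             (p[pc3] * std::pow(LH, p[pBetaExp]) - p[pc4] * LH) * y[iGrF];
  dy[iDomF] = p[pc4] * LH * y[iGrF] +
              (p[pd1] * std::pow(LH, p[pGammaExp]) - ovul) * y[iDomF];
  dy[iLut1] = ovul * y[iDomF] - p[pk1] * y[iLut1];
  dy[iLut2] = p[pk1] * y[iLut1] - p[pk2] * y[iLut2];
  dy[iLut3] = p[pk2] * y[iLut2] - p[pk3] * y[iLut3];
  dy[iLut4] = p[pk3] * y[iLut3] - p[pk4] * y[iLut4];
  dy[iInh] = p[pk_Inh] * (p[ph0] + p[ph1] * y[iDomF] + p[ph2] * y[iLut3] +
                          p[ph3] * y[iLut4] - y[iInh]);
}

// [[Rcpp::export]]
NumericVector cpp_cycle_rhs(double t, NumericVector y, double delayed_inh,
                            NumericVector params, NumericVector amp,
                            NumericVector phase, double exo_e2,
                            double exo_p4) {
  if (y.size() != NSTATE) stop("state vector must have length %d", NSTATE);
  if (params.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(y[i])) stop("non-finite state component at t=%g", t);
  NumericVector dy(NSTATE);
  rhs_core(t, y.begin(), delayed_inh, params.begin(), amp.begin(),
           phase.begin(), exo_e2, exo_p4, dy.begin());
  return dy;
}

// [[Rcpp::export]]
NumericVector cpp_pk_conc(NumericVector times, NumericVector dose_times,
                          NumericVector amounts, double ka, double a1,
                          double b1, double Nu, double Lu, double Mu) {
  PkDrug d;
  d.t_dose.assign(dose_times.begin(), dose_times.end());
  d.amount.assign(amounts.begin(), amounts.end());
  d.ka = ka; d.a1 = a1; d.b1 = b1; d.Nu = Nu; d.Lu = Lu; d.Mu = Mu;
  d.any = d.t_dose.size() > 0;
  NumericVector out(times.size());
  for (R_xlen_t i = 0; i < times.size(); ++i) out[i] = d.conc(times[i]);
  return out;
}

struct History {
  std::vector<double> t, inh, dinh;
  double t0, const_val;
  double lag(double tq) const {
    if (tq <= t0) return const_val;
    size_t hi = std::upper_bound(t.begin(), t.end(), tq) - t.begin();
    if (hi >= t.size()) hi = t.size() - 1;
    if (hi == 0) return const_val;
    size_t lo = hi - 1;
    double h = t[hi] - t[lo];
    if (h <= 0) return inh[lo];
    double s = (tq - t[lo]) / h;
    double h00 = (1 + 2 * s) * (1 - s) * (1 - s), h10 = s * (1 - s) * (1 - s),
           h01 = s * s * (3 - 2 * s), h11 = s * s * (s - 1);
    return h00 * inh[lo] + h * h10 * dinh[lo] + h01 * inh[hi] +
           h * h11 * dinh[hi];
  }
};

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1_ = 35.0 / 384, b3_ = 500.0 / 1113, b4_ = 125.0 / 192,
                    b5_ = -2187.0 / 6784, b6_ = 11.0 / 84;
static const double e1_ = 71.0 / 57600, e3_ = -71.0 / 16695, e4_ = 71.0 / 1920,
                    e5_ = -17253.0 / 339200, e6_ = 22.0 / 525, e7_ = -1.0 / 40;

// [[Rcpp::export]]
List cpp_simulate(NumericVector y0, double t0, double t_end,
                  NumericVector params, NumericVector amp, NumericVector phase,
                  NumericVector ee_dose_times, NumericVector ee_amounts,
                  NumericVector ee_pk, NumericVector dng_dose_times,
                  NumericVector dng_amounts, NumericVector dng_pk,
                  double out_dt, double rtol, double atol, double max_step) {
  if (y0.size() != NSTATE) stop("initial state must have length %d", NSTATE);
  if (params.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  if (t_end <= t0) stop("t_end must exceed t0");

  PkDrug ee, dng;
  ee.t_dose.assign(ee_dose_times.begin(), ee_dose_times.end());
  ee.amount.assign(ee_amounts.begin(), ee_amounts.end());
  ee.any = ee.t_dose.size() > 0;
  if (ee.any) {
    ee.ka = ee_pk[0]; ee.a1 = ee_pk[1]; ee.b1 = ee_pk[2];
    ee.Nu = ee_pk[3]; ee.Lu = ee_pk[4]; ee.Mu = ee_pk[5];
  }
  dng.t_dose.assign(dng_dose_times.begin(), dng_dose_times.end());
  dng.amount.assign(dng_amounts.begin(), dng_amounts.end());
  dng.any = dng.t_dose.size() > 0;
  if (dng.any) {
    dng.ka = dng_pk[0]; dng.a1 = dng_pk[1]; dng.b1 = dng_pk[2];
    dng.Nu = dng_pk[3]; dng.Lu = dng_pk[4]; dng.Mu = dng_pk[5];
  }

  const double* p = params.begin();
  const double* am = amp.begin();
  const double* ph = phase.begin();
  double tau = p[ptau];
  if (tau <= 0) stop("delay tau must be positive");

  History hist;
  hist.t0 = t0;
  hist.const_val = y0[iInh];

  std::vector<double> y(y0.begin(), y0.end()), ynew(NSTATE), yerr(NSTATE),
      ytmp(NSTATE);
  std::vector<std::array<double, NSTATE>> k(7);

  auto f = [&](double t, const double* yy, double* dy) {
    double lagv = hist.lag(t - tau);
    rhs_core(t, yy, lagv, p, am, ph, ee.conc(t), dng.conc(t), dy);
  };

  // output grid
  int nout = (int)std::floor((t_end - t0) / out_dt + 1e-9) + 1;
  NumericVector out_t(nout);
  NumericMatrix out_y(nout, NSTATE);
  for (int i = 0; i < nout; ++i) out_t[i] = t0 + i * out_dt;

  double t = t0;
  f(t, y.data(), k[0].data());
  hist.t.push_back(t);
  hist.inh.push_back(y[iInh]);
  hist.dinh.push_back(k[0][iInh]);
  for (int j = 0; j < NSTATE; ++j) out_y(0, j) = y[j];
  int iout = 1;

  double h = std::min(1e-3, max_step);
  long nstep = 0, nrej = 0;
  const long max_steps = 100000000L;

  while (t < t_end) {
    if (++nstep > max_steps) stop("step limit exceeded at t=%g", t);
    if (h > max_step) h = max_step;
    if (t + h > t_end) h = t_end - t;

    // DP stages
    for (int j = 0; j < NSTATE; ++j) ytmp[j] = y[j] + h * a21 * k[0][j];
    f(t + c2 * h, ytmp.data(), k[1].data());
    for (int j = 0; j < NSTATE; ++j)
      ytmp[j] = y[j] + h * (a31 * k[0][j] + a32 * k[1][j]);
    f(t + c3 * h, ytmp.data(), k[2].data());
    for (int j = 0; j < NSTATE; ++j)
      ytmp[j] = y[j] + h * (a41 * k[0][j] + a42 * k[1][j] + a43 * k[2][j]);
    f(t + c4 * h, ytmp.data(), k[3].data());
    for (int j = 0; j < NSTATE; ++j)
      ytmp[j] = y[j] + h * (a51 * k[0][j] + a52 * k[1][j] + a53 * k[2][j] +
                            a54 * k[3][j]);
    f(t + c5 * h, ytmp.data(), k[4].data());
    for (int j = 0; j < NSTATE; ++j)
      ytmp[j] = y[j] + h * (a61 * k[0][j] + a62 * k[1][j] + a63 * k[2][j] +
                            a64 * k[3][j] + a65 * k[4][j]);
    f(t + h, ytmp.data(), k[5].data());
    for (int j = 0; j < NSTATE; ++j)
      ynew[j] = y[j] + h * (b1_ * k[0][j] + b3_ * k[2][j] + b4_ * k[3][j] +
                            b5_ * k[4][j] + b6_ * k[5][j]);
    f(t + h, ynew.data(), k[6].data());

    double err = 0.0;
    bool finite = true;
    for (int j = 0; j < NSTATE; ++j) {
      double ej = h * (e1_ * k[0][j] + e3_ * k[2][j] + e4_ * k[3][j] +
                       e5_ * k[4][j] + e6_ * k[5][j] + e7_ * k[6][j]);
      double sk = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      if (!R_finite(ynew[j])) { finite = false; break; }
      err += (ej / sk) * (ej / sk);
    }
    err = finite ? std::sqrt(err / NSTATE) : 1e10;

    if (err <= 1.0) {
      // accept: dense output over [t, t+h] by cubic Hermite
      double tn = t + h;
      while (iout < nout && out_t[iout] <= tn + 1e-12) {
        double s = (out_t[iout] - t) / h;
        double h00 = (1 + 2 * s) * (1 - s) * (1 - s),
               h10 = s * (1 - s) * (1 - s), h01 = s * s * (3 - 2 * s),
               h11 = s * s * (s - 1);
        for (int j = 0; j < NSTATE; ++j)
          out_y(iout, j) = h00 * y[j] + h * h10 * k[0][j] + h01 * ynew[j] +
                           h * h11 * k[6][j];
        ++iout;
      }
      t = tn;
      y = ynew;
      for (int j = 0; j < NSTATE; ++j) k[0][j] = k[6][j];  // FSAL
      hist.t.push_back(t);
      hist.inh.push_back(y[iInh]);
      hist.dinh.push_back(k[0][iInh]);
      double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      ++nrej;
      if (nrej > max_steps) stop("too many rejected steps at t=%g", t);
      double fac = 0.9 * std::pow(err, -0.2);
      h *= std::max(0.1, fac);
      if (h < 1e-12)
        stop("integration failed: step size underflow at t=%g", t);
    }
  }

  return List::create(_["time"] = out_t, _["state"] = out_y,
                      _["n_steps"] = (double)nstep,
                      _["n_rejected"] = (double)nrej);
}
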