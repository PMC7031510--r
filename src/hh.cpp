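// Single-compartment conductance-based HVC_X neuron: fixed-step RK4 integrator.
//
// Units: mV, ms, pA, pF, nS, uM. Current balance:
//   Cm dV/dt = -(IL + IK + INa + ICaL + ICaT + IA + ISK + Ih) + Iapp
//
// The parameter vector P is packed by .hhParVector() on the R side; the
// index layout here and there must stay in step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// P layout ------------------------------------------------------------------
enum ParIndex {
  P_CM = 0,
  P_GNA, P_GK, P_GSK, P_GH, P_GCAT, P_GCAL, P_GA, P_GL,
  P_ENA, P_EK, P_EH, P_ECA, P_EL,
  P_M_HALF, P_M_SLOPE,
  P_H_HALF, P_H_SLOPE, P_TH_BASE, P_TH_AMP, P_TH_HALF, P_TH_SLOPE,
  P_N_HALF, P_N_SLOPE, P_TN_BASE, P_TN_AMP, P_TN_HALF, P_TN_SLOPE,
  P_A_HALF, P_A_SLOPE,
  P_B_HALF, P_B_SLOPE, P_TB_BASE, P_TB_AMP, P_TB_HALF, P_TB_SLOPE,
  P_S_HALF, P_S_SLOPE,
  P_E_HALF, P_E_SLOPE,
  P_R_HALF, P_R_SLOPE, P_TR_BASE, P_TR_AMP, P_TR_HALF, P_TR_SLOPE,
  P_KS, P_KCA, P_TAUCA, P_CA0,
  P_NPAR
};

static inline double sig(double v, double half, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - half) / slope));
}

// Voltage-dependent gating terms, evaluated either directly or via a
// linearly interpolated lookup table (the table is the hot path: a grid
// search integrates millions of steps).
struct Gates {
  double m3, hinf, tauh, ninf, taun, a2, binf, taub, s2, einf, rinf, taur;
};

static inline void gates_eval(const double *p, double v, Gates &g) {
  double m = sig(v, p[P_M_HALF], p[P_M_SLOPE]);
  g.m3   = m * m * m;
  g.hinf = sig(v, p[P_H_HALF], p[P_H_SLOPE]);
  g.tauh = p[P_TH_BASE] + p[P_TH_AMP] * sig(v, p[P_TH_HALF], p[P_TH_SLOPE]);
  g.ninf = sig(v, p[P_N_HALF], p[P_N_SLOPE]);
  g.taun = p[P_TN_BASE] + p[P_TN_AMP] * sig(v, p[P_TN_HALF], p[P_TN_SLOPE]);
  double a = sig(v, p[P_A_HALF], p[P_A_SLOPE]);
  g.a2   = a * a;
  g.binf = sig(v, p[P_B_HALF], p[P_B_SLOPE]);
  g.taub = p[P_TB_BASE] + p[P_TB_AMP] * sig(v, p[P_TB_HALF], p[P_TB_SLOPE]);
  double s = sig(v, p[P_S_HALF], p[P_S_SLOPE]);
  g.s2   = s * s;
  g.einf = sig(v, p[P_E_HALF], p[P_E_SLOPE]);
  g.rinf = sig(v, p[P_R_HALF], p[P_R_SLOPE]);
  g.taur = p[P_TR_BASE] + p[P_TR_AMP] * sig(v, p[P_TR_HALF], p[P_TR_SLOPE]);
}

// Lookup table over V in [V_LO, V_HI]
#define TAB_VLO (-160.0)
#define TAB_VHI (80.0)
#define TAB_STEP (0.05)
#define TAB_N (4801)

struct GateTable {
  std::vector<double> col[12];
  void build(const double *p) {
    for (int k = 0; k < 12; ++k) col[k].resize(TAB_N);
    Gates g;
    for (int i = 0; i < TAB_N; ++i) {
      double v = TAB_VLO + i * TAB_STEP;
      gates_eval(p, v, g);
      col[0][i] = g.m3;   col[1][i] = g.hinf; col[2][i] = g.tauh;
      col[3][i] = g.ninf; col[4][i] = g.taun; col[5][i] = g.a2;
      col[6][i] = g.binf; col[7][i] = g.taub; col[8][i] = g.s2;
      col[9][i] = g.einf; col[10][i] = g.rinf; col[11][i] = g.taur;
    }
  }
  inline void eval(double v, Gates &g) const {
    double x = (v - TAB_VLO) / TAB_STEP;
    if (x < 0.0) x = 0.0;
    if (x > TAB_N - 1.001) x = TAB_N - 1.001;
    int i = (int)x;
    double f = x - i;
    const double w = 1.0 - f;
    g.m3   = w * col[0][i] + f * col[0][i + 1];
    g.hinf = w * col[1][i] + f * col[1][i + 1];
    g.tauh = w * col[2][i] + f * col[2][i + 1];
    g.ninf = w * col[3][i] + f * col[3][i + 1];
    g.taun = w * col[4][i] + f * col[4][i + 1];
    g.a2   = w * col[5][i] + f * col[5][i + 1];
    g.binf = w * col[6][i] + f * col[6][i + 1];
    g.taub = w * col[7][i] + f * col[7][i + 1];
    g.s2   = w * col[8][i] + f * col[8][i + 1];
    g.einf = w * col[9][i] + f * col[9][i + 1];
    g.rinf = w * col[10][i] + f * col[10][i + 1];
    g.taur = w * col[11][i] + f * col[11][i + 1];
  }
};

// state y = {V, h, n, b, r, Ca}
static inline void deriv(const double *p, const GateTable &tab,
                         const double *y, double iapp, double *dy) {
  const double v = y[0], h = y[1], n = y[2], b = y[3], r = y[4], ca = y[5];
  Gates g;
  tab.eval(v, g);
  const double n2 = n * n;
  const double ina  = p[P_GNA] * g.m3 * h * (v - p[P_ENA]);
  const double ik   = p[P_GK] * n2 * n2 * (v - p[P_EK]);
  const double ical = p[P_GCAL] * g.s2 * (v - p[P_ECA]);
  const double icat = p[P_GCAT] * g.a2 * b * (v - p[P_ECA]);
  const double ia   = p[P_GA] * g.einf * (v - p[P_EK]);
  const double ks   = p[P_KS];
  const double sk   = ca * ca / (ca * ca + ks * ks);
  const double isk  = p[P_GSK] * sk * (v - p[P_EK]);
  const double ih   = p[P_GH] * r * (v - p[P_EH]);
  const double il   = p[P_GL] * (v - p[P_EL]);
  dy[0] = (-(il + ik + ina + ical + icat + ia + isk + ih) + iapp) / p[P_CM];
  dy[1] = (g.hinf - h) / g.tauh;
  dy[2] = (g.ninf - n) / g.taun;
  dy[3] = (g.binf - b) / g.taub;
  dy[4] = (g.rinf - r) / g.taur;
  dy[5] = -p[P_KCA] * (icat + ical) - (ca - p[P_CA0]) / p[P_TAUCA];
}

//' @useDynLib hvcx, .registration = TRUE
// [[Rcpp::export(name = ".hh_integrate")]]
List hh_integrate(NumericVector P, NumericVector y0, NumericVector iapp,
                  double dt) {
  if (P.size() != P_NPAR) stop("parameter vector has wrong length");
  if (y0.size() != 6) stop("state vector must have length 6");
  const int n = iapp.size();
  const double *p = &P[0];
  GateTable tab;
  tab.build(p);

  NumericVector v_out(n);
  double y[6], k1[6], k2[6], k3[6], k4[6], yt[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  v_out[0] = y[0];
  bool diverged = false;
  int div_at = -1;

  for (int i = 1; i < n; ++i) {
    // current is piecewise-constant over [t_{i-1}, t_i): step stimuli are
    // then represented exactly and RK4 keeps its full order across edges
    const double i0 = iapp[i - 1];
    deriv(p, tab, y, i0, k1);
    for (int j = 0; j < 6; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    deriv(p, tab, yt, i0, k2);
    for (int j = 0; j < 6; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    deriv(p, tab, yt, i0, k3);
    for (int j = 0; j < 6; ++j) yt[j] = y[j] + dt * k3[j];
    deriv(p, tab, yt, i0, k4);
    for (int j = 0; j < 6; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    v_out[i] = y[0];
    if (!std::isfinite(y[0]) || std::fabs(y[0]) > 200.0) {
      diverged = true;
      div_at = i;
      break;
    }
  }

  NumericVector yf(6);
  for (int j = 0; j < 6; ++j) yf[j] = y[j];
  return List::create(_["voltage"] = v_out, _["state"] = yf,
                      _["diverged"] = diverged, _["divergedAt"] = div_at + 1);
}

// Steady state at clamped voltage v: all gates at their steady-state values,
// calcium at the fixed point of its pool equation. Returns the state vector
// and the total ionic current (= the applied current that holds v).
// [[Rcpp::export(name = ".hh_steady_state")]]
List hh_steady_state(NumericVector P, double v) {
  if (P.size() != P_NPAR) stop("parameter vector has wrong length");
  const double *p = &P[0];
  Gates g;
  gates_eval(p, v, g);
  const double ical = p[P_GCAL] * g.s2 * (v - p[P_ECA]);
  const double icat = p[P_GCAT] * g.a2 * g.binf * (v - p[P_ECA]);
  const double ca = p[P_CA0] - p[P_KCA] * p[P_TAUCA] * (icat + ical);
  const double n2 = g.ninf * g.ninf;
  const double ina = p[P_GNA] * g.m3 * g.hinf * (v - p[P_ENA]);
  const double ik  = p[P_GK] * n2 * n2 * (v - p[P_EK]);
  const double ia  = p[P_GA] * g.einf * (v - p[P_EK]);
  const double sk  = ca * ca / (ca * ca + p[P_KS] * p[P_KS]);
  const double isk = p[P_GSK] * sk * (v - p[P_EK]);
  const double ih  = p[P_GH] * g.rinf * (v - p[P_EH]);
  const double il  = p[P_GL] * (v - p[P_EL]);
  const double itot = il + ik + ina + ical + icat + ia + isk + ih;
  NumericVector y(6);
  y[0] = v; y[1] = g.hinf; y[2] = g.ninf; y[3] = g.binf; y[4] = g.rinf; y[5] = ca;
  return List::create(_["state"] = y, _["current"] = itot);
}

// Spike onsets by upward crossings of a smoothed dV/dt threshold.
//
// Rule (single implementation, used both by detectSpikes() and by the
// grid-search disregard fast path):
//   * slope_i = (v[i] - v[i-k]) / (k*dt) with k spanning ~0.2 ms (noise
//     robustness for additive voltage noise);
//   * an onset is the first sample where slope >= dvdt_thresh after being
//     below it;
//   * onsets closer than `refractory` ms to the previous accepted onset are
//     merged (dropped);
//   * the voltage must rise by >= min_rise mV within `rise_win` ms of the
//     onset, otherwise the crossing is discarded as noise.
// Returns 1-based onset indices; i_from/i_to are 1-based inclusive bounds.
// [[Rcpp::export(name = ".hh_spike_onsets")]]
IntegerVector hh_spike_onsets(NumericVector v, double dt, double dvdt_thresh,
                              double refractory, double min_rise,
                              double rise_win, int i_from, int i_to) {
  const int n = v.size();
  int k = (int)std::lround(0.2 / dt);
  if (k < 1) k = 1;
  int lo = std::max(i_from - 1, k);   // 0-based start so v[i-k] exists
  int hi = std::min(i_to, n);         // 0-based exclusive end
  const int rise_n = (int)std::lround(rise_win / dt);
  std::vector<int> onsets;
  double last = -1e9;
  bool below = true;
  for (int i = lo; i < hi; ++i) {
    const double slope = (v[i] - v[i - k]) / (k * dt);
    if (below && slope >= dvdt_thresh) {
      below = false;
      const double t = i * dt;
      if (t - last >= refractory) {
        // validate: genuine upstroke must actually rise
        double vmax = v[i];
        const int jmax = std::min(i + rise_n, n - 1);
        for (int j = i + 1; j <= jmax; ++j)
          if (v[j] > vmax) vmax = v[j];
        if (vmax - v[i] >= min_rise) {
          onsets.push_back(i + 1);  // to 1-based
          last = t;
        }
      }
    } else if (slope < dvdt_thresh) {
      below = true;
    }
  }
  return wrap(onsets);
}
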