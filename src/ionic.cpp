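// Cell-level electrophysiology kernels.
//
// Two membrane models are provided:
//  * the Courtemanche-Ramirez-Nattel (CRN) human atrial model (21 state
//    variables), integrated with Rush-Larsen updates for the Hodgkin-Huxley
//    gates and forward Euler for voltage and concentrations;
//  * a Mitchell-Schaeffer two-variable excitable surrogate for cheap tests.
//
// State is stored node-major as an R matrix (rows = nodes, columns = state
// variables) and updated in place so the tissue solver can alternate
// reaction and diffusion steps without copying.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// CRN constants (published formulation; units: mV, ms, mM, pA/pF)
// ---------------------------------------------------------------------------

static const double R_GAS = 8.3143;
static const double TEMP  = 310.0;
static const double FDY   = 96.4867;
static const double CM    = 100.0;     // pF
static const double V_I   = 13668.0;   // um^3
static const double V_UP  = 1109.52;
static const double V_REL = 96.48;
static const double K_O   = 5.4;
static const double NA_O  = 140.0;
static const double CA_O  = 1.8;
static const double G_NA  = 7.8;
static const double G_K1  = 0.09;
static const double G_TO  = 0.1652;
static const double G_KR  = 0.029411765;
static const double G_KS  = 0.12941176;
static const double G_CAL = 0.12375;
static const double G_BCA = 0.001131;
static const double G_BNA = 0.0006744375;
static const double I_NAK_MAX  = 0.59933874;
static const double KM_NA_I    = 10.0;
static const double KM_K_O     = 1.5;
static const double I_NACA_MAX = 1600.0;
static const double KM_NA      = 87.5;
static const double KM_CA      = 1.38;
static const double K_SAT      = 0.1;
static const double GAMMA      = 0.35;
static const double I_PCA_MAX  = 0.275;
static const double I_UP_MAX   = 0.005;
static const double K_UP       = 0.00092;
static const double CA_UP_MAX  = 15.0;
static const double K_REL      = 30.0;
static const double TAU_TR     = 180.0;
static const double TAU_U      = 8.0;
static const double TAU_FCA    = 2.0;
static const double TRPN_MAX   = 0.07;
static const double KM_TRPN    = 0.0005;
static const double CMDN_MAX   = 0.05;
static const double KM_CMDN    = 0.00238;
static const double CSQN_MAX   = 10.0;
static const double KM_CSQN    = 0.8;
static const double KQ10       = 3.0;

// state column indices
enum { iV, iM, iH, iJ, iOA, iOI, iUA, iUI, iXR, iXS, iD, iF, iFCA,
       iU, iVG, iW, iNAI, iKI, iCAI, iCAUP, iCAREL, NSTATE };

// conductance-multiplier indices (order shared with the R side)
enum { mNA, mK1, mTO, mKUR, mCAL, mKR, mKS, mBNA, mBCA, mNAK, mNACA, mPCA,
       NMULT };

// [[Rcpp::export]]
NumericVector crn_initial_state() {
  NumericVector s(NSTATE);
  s[iV] = -81.18;  s[iM] = 2.908e-3; s[iH] = 9.649e-1; s[iJ] = 9.775e-1;
  s[iOA] = 3.043e-2; s[iOI] = 9.992e-1; s[iUA] = 4.966e-3; s[iUI] = 9.986e-1;
  s[iXR] = 3.296e-5; s[iXS] = 1.869e-2; s[iD] = 1.367e-4; s[iF] = 9.996e-1;
  s[iFCA] = 7.755e-1; s[iU] = 0.0; s[iVG] = 1.0; s[iW] = 9.992e-1;
  s[iNAI] = 11.17; s[iKI] = 139.0; s[iCAI] = 1.013e-4;
  s[iCAUP] = 1.488; s[iCAREL] = 1.488;
  s.attr("names") = CharacterVector::create(
    "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fCa",
    "u", "v", "w", "Nai", "Ki", "Cai", "Ca_up", "Ca_rel");
  return s;
}

struct GateUpdate { double inf, tau; };

static inline double safe_ratio(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// one Rush-Larsen / Euler step for a single node; `s` points at the 21
// state values (strided by `n` across columns), `g` at the 12 multipliers.
static inline void crn_node_step(double* sbase, R_xlen_t node, R_xlen_t n,
                                 const double* g, double stim, double dt) {
  #define S(k) sbase[node + (R_xlen_t)(k) * n]
  double V = S(iV);
  const double rtf = R_GAS * TEMP / FDY;
  double ENa = rtf * std::log(NA_O / S(iNAI));
  double EK  = rtf * std::log(K_O / S(iKI));
  double ECa = 0.5 * rtf * std::log(CA_O / S(iCAI));

  double INa = g[mNA] * G_NA * S(iM)*S(iM)*S(iM) * S(iH) * S(iJ) * (V - ENa);
  double IK1 = g[mK1] * G_K1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  double Ito = g[mTO] * G_TO * S(iOA)*S(iOA)*S(iOA) * S(iOI) * (V - EK);
  double gKur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  double IKur = g[mKUR] * gKur * S(iUA)*S(iUA)*S(iUA) * S(iUI) * (V - EK);
  double IKr = g[mKR] * G_KR * S(iXR) * (V - EK) /
               (1.0 + std::exp((V + 15.0) / 22.4));
  double IKs = g[mKS] * G_KS * S(iXS)*S(iXS) * (V - EK);
  double ICaL = g[mCAL] * G_CAL * S(iD) * S(iF) * S(iFCA) * (V - 65.0);
  double IpCa = g[mPCA] * I_PCA_MAX * S(iCAI) / (0.0005 + S(iCAI));

  double vfrt = V / rtf;
  double sigma = (std::exp(NA_O / 67.3) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                       0.0365 * sigma * std::exp(-vfrt));
  double INaK = g[mNAK] * I_NAK_MAX * fNaK /
                (1.0 + std::pow(KM_NA_I / S(iNAI), 1.5)) *
                (K_O / (K_O + KM_K_O));
  double nai3 = S(iNAI)*S(iNAI)*S(iNAI);
  double nao3 = NA_O*NA_O*NA_O;
  double INaCa = g[mNACA] * I_NACA_MAX *
    (std::exp(GAMMA * vfrt) * nai3 * CA_O -
     std::exp((GAMMA - 1.0) * vfrt) * nao3 * S(iCAI)) /
    ((KM_NA*KM_NA*KM_NA + nao3) * (KM_CA + CA_O) *
     (1.0 + K_SAT * std::exp((GAMMA - 1.0) * vfrt)));
  double IbNa = g[mBNA] * G_BNA * (V - ENa);
  double IbCa = g[mBCA] * G_BCA * (V - ECa);

  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
                INaCa + IbNa + IbCa;

  // SR fluxes
  double Irel = K_REL * S(iU)*S(iU) * S(iVG) * S(iW) * (S(iCAREL) - S(iCAI));
  double Itr  = (S(iCAUP) - S(iCAREL)) / TAU_TR;
  double Iup  = I_UP_MAX / (1.0 + K_UP / S(iCAI));
  double Iupleak = I_UP_MAX * S(iCAUP) / CA_UP_MAX;

  // gate rates
  GateUpdate gu[13];
  { // m
    double a = safe_ratio(0.32 * (V + 47.13),
                          1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
    double b = 0.08 * std::exp(-V / 11.0);
    gu[0].inf = a / (a + b); gu[0].tau = 1.0 / (a + b);
  }
  { // h
    double a, b;
    if (V >= -40.0) { a = 0.0;
      b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      a = 0.135 * std::exp(-(V + 80.0) / 6.8);
      b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    }
    gu[1].inf = a / (a + b); gu[1].tau = 1.0 / (a + b);
  }
  { // j
    double a, b;
    if (V >= -40.0) { a = 0.0;
      b = 0.3 * std::exp(-2.535e-7 * V) /
          (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      a = (-1.2714e5 * std::exp(0.2444 * V) -
           3.474e-5 * std::exp(-0.04391 * V)) * (V + 37.78) /
          (1.0 + std::exp(0.311 * (V + 79.23)));
      b = 0.1212 * std::exp(-0.01052 * V) /
          (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    gu[2].inf = a / (a + b); gu[2].tau = 1.0 / (a + b);
  }
  { // oa
    double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) +
                       std::exp(-(V - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    gu[3].inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
    gu[3].tau = 1.0 / ((a + b) * KQ10);
  }
  { // oi
    double a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
    double b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
    gu[4].inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
    gu[4].tau = 1.0 / ((a + b) * KQ10);
  }
  { // ua
    double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) +
                       std::exp(-(V - 30.0) / 59.0));
    double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
    gu[5].inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
    gu[5].tau = 1.0 / ((a + b) * KQ10);
  }
  { // ui
    double a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
    double b = std::exp((V - 158.0) / 16.0);
    gu[6].inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
    gu[6].tau = 1.0 / ((a + b) * KQ10);
  }
  { // xr
    double a = safe_ratio(0.0003 * (V + 14.1),
                          1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
    double b = safe_ratio(7.3898e-5 * (V - 3.3328),
                          std::exp((V - 3.3328) / 5.1237) - 1.0,
                          7.3898e-5 * 5.1237);
    gu[7].inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
    gu[7].tau = 1.0 / (a + b);
  }
  { // xs
    double a = safe_ratio(4e-5 * (V - 19.9),
                          1.0 - std::exp(-(V - 19.9) / 17.0), 4e-5 * 17.0);
    double b = safe_ratio(3.5e-5 * (V - 19.9),
                          std::exp((V - 19.9) / 9.0) - 1.0, 3.5e-5 * 9.0);
    gu[8].inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
    gu[8].tau = 0.5 / (a + b);
  }
  { // d
    double x = V + 10.0;
    double e = std::exp(-x / 6.24);
    gu[9].inf = 1.0 / (1.0 + std::exp(-x / 8.0));
    gu[9].tau = std::fabs(x) < 1e-10
      ? 1.0 / (0.035 * 6.24 * 2.0)
      : (1.0 - e) / (0.035 * x * (1.0 + e));
  }
  { // f
    gu[10].inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
    gu[10].tau = 9.0 /
      (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  }
  { // fCa
    gu[11].inf = 1.0 / (1.0 + S(iCAI) / 0.00035);
    gu[11].tau = TAU_FCA;
  }
  { // w
    double x = V - 7.9;
    double e = std::exp(-x / 5.0);
    gu[12].inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
    gu[12].tau = std::fabs(x) < 1e-10
      ? 6.0 * 0.2 / 1.3
      : 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * x);
  }

  // Ca-release gates driven by Fn
  double Fn = 1e3 * (1e-15 * V_REL * Irel -
                     1e-15 / (2.0 * FDY) * (0.5 * ICaL * CM -
                                            0.2 * INaCa * CM));
  double u_inf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tau_v = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));

  // concentration derivatives (forward Euler)
  double dNai = CM * (-3.0 * INaK - (3.0 * INaCa + IbNa + INa)) / (FDY * V_I);
  double dKi  = CM * (2.0 * INaK - (IK1 + Ito + IKur + IKr + IKs)) /
                (FDY * V_I);
  double cai = S(iCAI);
  double B1 = (2.0 * INaCa - (IpCa + ICaL + IbCa)) * CM / (2.0 * FDY * V_I) +
              (V_UP * (Iupleak - Iup) + Irel * V_REL) / V_I;
  double B2 = 1.0 + TRPN_MAX * KM_TRPN / ((cai + KM_TRPN) * (cai + KM_TRPN)) +
              CMDN_MAX * KM_CMDN / ((cai + KM_CMDN) * (cai + KM_CMDN));
  double dCaup  = Iup - (Iupleak + Itr * V_REL / V_UP);
  double carel  = S(iCAREL);
  double dCarel = (Itr - Irel) /
    (1.0 + CSQN_MAX * KM_CSQN / ((carel + KM_CSQN) * (carel + KM_CSQN)));

  // apply updates
  S(iV) += dt * (-Iion + stim);
  static const int gidx[13] = { iM, iH, iJ, iOA, iOI, iUA, iUI, iXR, iXS,
                                iD, iF, iFCA, iW };
  for (int k = 0; k < 13; ++k) {
    double old = S(gidx[k]);
    S(gidx[k]) = gu[k].inf + (old - gu[k].inf) * std::exp(-dt / gu[k].tau);
  }
  S(iU)  = u_inf + (S(iU) - u_inf) * std::exp(-dt / TAU_U);
  S(iVG) = v_inf + (S(iVG) - v_inf) * std::exp(-dt / tau_v);
  S(iNAI)   += dt * dNai;
  S(iKI)    += dt * dKi;
  S(iCAI)   += dt * B1 / B2;
  S(iCAUP)  += dt * dCaup;
  S(iCAREL) += dt * dCarel;
  #undef S
}

// Advance all nodes by nsub substeps of length dt. `mult` is either a
// 12-vector (shared) or an n x 12 matrix (per node); `stim` is per node
// in uA/uF (constant over the step).
// [[Rcpp::export]]
void crn_step_inplace(NumericMatrix state, NumericMatrix mult,
                      NumericVector stim, double dt, int nsub) {
  R_xlen_t n = state.nrow();
  if (state.ncol() != NSTATE) stop("state must have 21 columns");
  if (mult.ncol() != NMULT) stop("multiplier matrix must have 12 columns");
  bool shared = (mult.nrow() == 1);
  if (!shared && mult.nrow() != n) stop("multiplier rows must match nodes");
  double* sp = REAL(state);
  double g[NMULT];
  for (int s = 0; s < nsub; ++s) {
    for (R_xlen_t i = 0; i < n; ++i) {
      for (int k = 0; k < NMULT; ++k)
        g[k] = shared ? mult(0, k) : mult(i, k);
      crn_node_step(sp, i, n, g, stim[i], dt);
      if (!std::isfinite(sp[i])) {
        stop("CRN state became non-finite at node %d", (int)(i + 1));
      }
    }
  }
}

// Time-derivative of the CRN state (limit of one integration step as
// dt -> 0; the Rush-Larsen gate update tends to the exact (inf-g)/tau).
// [[Rcpp::export]]
NumericVector crn_rhs_cpp(NumericVector state, NumericVector mult,
                          double stim) {
  const double dt = 1e-6;
  NumericMatrix s(1, NSTATE);
  for (int k = 0; k < NSTATE; ++k) s(0, k) = state[k];
  double g[NMULT];
  for (int k = 0; k < NMULT; ++k) g[k] = mult[k];
  crn_node_step(REAL(s), 0, 1, g, stim, dt);
  NumericVector out(NSTATE);
  for (int k = 0; k < NSTATE; ++k) out[k] = (s(0, k) - state[k]) / dt;
  out.attr("names") = crn_initial_state().attr("names");
  return out;
}

// Single-cell pacing entirely in C++: returns the sampled voltage trace of
// the whole run. Stimulus is a square pulse at each beat onset.
// [[Rcpp::export]]
List crn_pace_cpp(NumericVector mult, double cl, int nbeats, double dt,
                  double stim_amp, double stim_dur, double sample_dt,
                  Nullable<NumericVector> init = R_NilValue) {
  NumericVector s0 = init.isNull() ? crn_initial_state()
                                   : NumericVector(init.get());
  NumericMatrix state(1, NSTATE);
  for (int k = 0; k < NSTATE; ++k) state(0, k) = s0[k];
  NumericMatrix m(1, NMULT);
  for (int k = 0; k < NMULT; ++k) m(0, k) = mult[k];

  double tend = cl * nbeats;
  R_xlen_t nsamp = (R_xlen_t)std::floor(tend / sample_dt) + 1;
  NumericVector tv(nsamp), vv(nsamp);
  R_xlen_t isamp = 0;
  long nstep = (long)std::llround(tend / dt);
  NumericVector stim(1);
  double* sp = REAL(state);
  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    if (isamp < nsamp && t + 1e-9 >= isamp * sample_dt) {
      tv[isamp] = t; vv[isamp] = state(0, iV); ++isamp;
    }
    if (step == nstep) break;
    double tb = t - cl * std::floor(t / cl);
    stim[0] = (tb < stim_dur) ? stim_amp : 0.0;
    double g[NMULT];
    for (int k = 0; k < NMULT; ++k) g[k] = m(0, k);
    crn_node_step(sp, 0, 1, g, stim[0], dt);
    if (!std::isfinite(state(0, iV))) stop("CRN voltage non-finite at t=%f", t);
  }
  return List::create(_["t"] = tv[Range(0, isamp - 1)],
                      _["V"] = vv[Range(0, isamp - 1)],
                      _["state"] = state);
}

// ---------------------------------------------------------------------------
// Mitchell-Schaeffer two-variable surrogate
// state columns: u (normalized voltage, 0..1), h (recovery gate)
// params: tau_in, tau_out, tau_open, tau_close, u_gate
// mult columns: tau_close multiplier, tau_in multiplier (per node or shared)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void ms_step_inplace(NumericMatrix state, NumericMatrix mult,
                     NumericVector stim, NumericVector params,
                     double dt, int nsub) {
  R_xlen_t n = state.nrow();
  if (state.ncol() != 2) stop("surrogate state must have 2 columns");
  bool shared = (mult.nrow() == 1);
  double tin0 = params[0], tout = params[1], topen = params[2],
         tclose0 = params[3], ugate = params[4];
  double* u = REAL(state);
  double* h = u + n;
  for (int s = 0; s < nsub; ++s) {
    for (R_xlen_t i = 0; i < n; ++i) {
      double tclose = tclose0 * (shared ? mult(0, 0) : mult(i, 0));
      double tin = tin0 * (shared ? mult(0, 1) : mult(i, 1));
      double ui = u[i], hi = h[i];
      double du = hi * ui * ui * (1.0 - ui) / tin - ui / tout + stim[i];
      double dh = (ui < ugate) ? (1.0 - hi) / topen : -hi / tclose;
      u[i] = ui + dt * du;
      h[i] = hi + dt * dh;
      if (u[i] < -0.2) u[i] = -0.2;
      if (u[i] > 1.5) u[i] = 1.5;
    }
  }
}

// [[Rcpp::export]]
List ms_pace_cpp(NumericVector mult, NumericVector params, double cl,
                 int nbeats, double dt, double stim_amp, double stim_dur,
                 double sample_dt) {
  NumericMatrix state(1, 2);
  state(0, 0) = 0.0; state(0, 1) = 1.0;
  NumericMatrix m(1, 2);
  m(0, 0) = mult[0]; m(0, 1) = mult[1];
  double tend = cl * nbeats;
  R_xlen_t nsamp = (R_xlen_t)std::floor(tend / sample_dt) + 1;
  NumericVector tv(nsamp), vv(nsamp), stim(1);
  R_xlen_t isamp = 0;
  long nstep = (long)std::llround(tend / dt);
  double tin = params[0] * mult[1], tout = params[1], topen = params[2],
         tclose = params[3] * mult[0], ugate = params[4];
  double u = 0.0, hh = 1.0;
  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    if (isamp < nsamp && t + 1e-9 >= isamp * sample_dt) {
      tv[isamp] = t; vv[isamp] = u; ++isamp;
    }
    if (step == nstep) break;
    double tb = t - cl * std::floor(t / cl);
    double is = (tb < stim_dur) ? stim_amp : 0.0;
    double du = hh * u * u * (1.0 - u) / tin - u / tout + is;
    double dh = (u < ugate) ? (1.0 - hh) / topen : -hh / tclose;
    u += dt * du; hh += dt * dh;
    if (u < -0.2) u = -0.2;
    if (u > 1.5) u = 1.5;
  }
  state(0, 0) = u; state(0, 1) = hh;
  return List::create(_["t"] = tv[Range(0, isamp - 1)],
                      _["V"] = vv[Range(0, isamp - 1)],
                      _["state"] = state);
}

// ---------------------------------------------------------------------------
// Small numeric helpers used by the analysis modules
// ---------------------------------------------------------------------------

// Overwrite one column of a matrix without duplicating it (the tissue
// solver owns its state matrix and updates the voltage column each step).
// [[Rcpp::export]]
void set_col_inplace(NumericMatrix m, int j, NumericVector v) {
  R_xlen_t n = m.nrow();
  if (v.size() != n) stop("column length mismatch");
  double* dst = REAL(m) + (R_xlen_t)(j - 1) * n;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = v[i];
}

// Count threshold upcrossings per node (activations). v is an ntime x nnode
// matrix; returns per-node counts of upward crossings of `thr`.
// [[Rcpp::export]]
IntegerVector count_upcrossings(NumericMatrix v, double thr) {
  R_xlen_t nt = v.nrow(), nn = v.ncol();
  IntegerVector out(nn);
  for (R_xlen_t j = 0; j < nn; ++j) {
    int c = 0;
    for (R_xlen_t i = 1; i < nt; ++i)
      if (v(i - 1, j) < thr && v(i, j) >= thr) ++c;
    out[j] = c;
  }
  return out;
}

// First activation time per node: the upstroke must cross `thr` upward
// (rejecting subthreshold wiggle); the reported time is the linearly
// interpolated threshold crossing, which is sub-sample accurate and, for
// identical waveforms at two probes, cancels exactly in CV differences.
// NA if the node never activates. t is the sample-time vector.
// [[Rcpp::export]]
NumericVector first_activation_time(NumericMatrix v, NumericVector t,
                                    double thr) {
  R_xlen_t nt = v.nrow(), nn = v.ncol();
  NumericVector out(nn, NA_REAL);
  for (R_xlen_t j = 0; j < nn; ++j) {
    for (R_xlen_t i = 1; i < nt; ++i) {
      if (v(i - 1, j) < thr && v(i, j) >= thr) {
        double f = (thr - v(i - 1, j)) / (v(i, j) - v(i - 1, j));
        out[j] = t[i - 1] + f * (t[i] - t[i - 1]);
        break;
      }
    }
  }
  return out;
}
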