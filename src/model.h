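// Internal representation of a 3-compartment conductance-based neuron model,
// shared by the production integrator and the independent RK4 reference
// integrator. Units: mV, ms, nS, pA, pF (nS*mV = pA, pF*mV/ms = pA).
#ifndef VCLAMP_MODEL_H
#define VCLAMP_MODEL_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

namespace vclamp {

constexpr int N_COMP = 3; // 0 = soma, 1 = axon, 2 = dendrite

struct GateParams {
  double v_half, v_slope, tau_max, tau_min, v_tau_half, v_tau_slope;
};

inline double gate_inf(double v, const GateParams &g) {
  return 0.5 + 0.5 * std::tanh((v - g.v_half) / g.v_slope);
}

inline double gate_tau(double v, const GateParams &g) {
  double t = std::tanh((v - g.v_tau_half) / g.v_tau_slope);
  return (g.tau_max - g.tau_min) * (1.0 - t * t) + g.tau_min;
}

struct Current {
  double e_rev;
  int p;                 // activation exponent
  bool kca;              // Ca-activated (no voltage gating)
  bool ca_source;        // contributes to Ca influx
  bool has_inact;
  double g[N_COMP];      // absolute conductance per compartment, nS
  GateParams act, inact;
  int m_idx[N_COMP], h_idx[N_COMP]; // state indices (-1 when absent)
};

struct SynParams {
  double e_exc, e_inh, tau, v_th, v_slope;
};

struct Model {
  double cap[N_COMP], g_leak[N_COMP], e_leak, g_sx, g_sd;
  std::vector<Current> cur;
  bool has_ca;
  double ca_gain, ca_rest, ca_tau, ca_khalf;
  int ca_idx;            // start of Ca[3] block, -1 when absent
  int se_idx, si_idx;    // synaptic activation states
  int n_state;
};

// Flat state vector layout: V[3], then gating states in current order
// (per compartment with g > 0, activation then inactivation), then Ca[3]
// when a Ca pool is present, then S_exc, S_inh.
inline Model parse_model(const Rcpp::List &ml) {
  Model M;
  Rcpp::NumericVector cap = ml["cap"], gl = ml["g_leak"];
  for (int c = 0; c < N_COMP; ++c) { M.cap[c] = cap[c]; M.g_leak[c] = gl[c]; }
  M.e_leak = Rcpp::as<double>(ml["e_leak"]);
  M.g_sx = Rcpp::as<double>(ml["g_sx"]);
  M.g_sd = Rcpp::as<double>(ml["g_sd"]);

  int idx = N_COMP;
  Rcpp::List curs = ml["currents"];
  for (int i = 0; i < curs.size(); ++i) {
    Rcpp::List cl = curs[i];
    Current C;
    C.e_rev = Rcpp::as<double>(cl["e_rev"]);
    C.p = Rcpp::as<int>(cl["p"]);
    C.kca = Rcpp::as<bool>(cl["kca"]);
    C.ca_source = Rcpp::as<bool>(cl["ca_source"]);
    Rcpp::NumericVector g = cl["g"];
    for (int c = 0; c < N_COMP; ++c) C.g[c] = g[c];
    auto read_gate = [](Rcpp::NumericVector v) {
      GateParams gp;
      gp.v_half = v[0]; gp.v_slope = v[1]; gp.tau_max = v[2];
      gp.tau_min = v[3]; gp.v_tau_half = v[4]; gp.v_tau_slope = v[5];
      return gp;
    };
    if (!C.kca) C.act = read_gate(cl["act"]);
    C.has_inact = cl.containsElementNamed("inact") &&
                  !Rf_isNull(cl["inact"]);
    if (C.has_inact) C.inact = read_gate(cl["inact"]);
    for (int c = 0; c < N_COMP; ++c) {
      C.m_idx[c] = C.h_idx[c] = -1;
      if (C.g[c] > 0.0 && !C.kca) {
        C.m_idx[c] = idx++;
        if (C.has_inact) C.h_idx[c] = idx++;
      }
    }
    M.cur.push_back(C);
  }

  M.has_ca = ml.containsElementNamed("calcium") && !Rf_isNull(ml["calcium"]);
  M.ca_idx = -1;
  M.ca_gain = M.ca_rest = M.ca_khalf = 0.0; M.ca_tau = 1.0;
  if (M.has_ca) {
    Rcpp::List ca = ml["calcium"];
    M.ca_gain = Rcpp::as<double>(ca["gain"]);
    M.ca_rest = Rcpp::as<double>(ca["rest"]);
    M.ca_tau = Rcpp::as<double>(ca["tau"]);
    M.ca_khalf = Rcpp::as<double>(ca["kca_half"]);
    M.ca_idx = idx; idx += N_COMP;
  }
  M.se_idx = idx++; M.si_idx = idx++;
  M.n_state = idx;
  return M;
}

inline SynParams parse_syn(const Rcpp::List &sl) {
  SynParams S;
  S.e_exc = Rcpp::as<double>(sl["e_exc"]);
  S.e_inh = Rcpp::as<double>(sl["e_inh"]);
  S.tau = Rcpp::as<double>(sl["tau"]);
  S.v_th = Rcpp::as<double>(sl["v_th"]);
  S.v_slope = Rcpp::as<double>(sl["v_slope"]);
  return S;
}

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

// Synaptic drive steady state with guard keeping the effective time
// constant tau*(1 - S_inf) positive.
inline double syn_inf(double v_pre, const SynParams &S) {
  if (v_pre <= S.v_th) return 0.0;
  double s = std::tanh((v_pre - S.v_th) / S.v_slope);
  const double cap = 1.0 - 1e-6;
  return s > cap ? cap : s;
}

} // namespace vclamp

#endif
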