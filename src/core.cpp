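// Production integrator: exponential-Euler updates for gating and synaptic
// activation, forward-Euler voltage updates, fixed step. Gating steady states
// and per-step decay factors are evaluated through fine voltage lookup tables
// (0.02 mV grid, linear interpolation) built once per run.
#include "model.h"
using namespace Rcpp;
using namespace vclamp;

namespace {

constexpr double V_MIN = -200.0, V_MAX = 100.0, V_STEP = 0.02;
constexpr int V_N = 15001;

struct GateTable {
  std::vector<double> xinf, edt;
  void build(const GateParams &g, double dt) {
    xinf.resize(V_N); edt.resize(V_N);
    for (int i = 0; i < V_N; ++i) {
      double v = V_MIN + i * V_STEP;
      xinf[i] = gate_inf(v, g);
      edt[i] = std::exp(-dt / gate_tau(v, g));
    }
  }
  inline void lookup(double v, double &xi, double &ed) const {
    double u = (v - V_MIN) / V_STEP;
    // !(u > 0) also catches NaN voltages from diverging trajectories
    if (!(u > 0.0)) { xi = xinf[0]; ed = edt[0]; return; }
    if (u >= V_N - 1) { xi = xinf[V_N - 1]; ed = edt[V_N - 1]; return; }
    int i = static_cast<int>(u);
    double f = u - i;
    xi = xinf[i] + f * (xinf[i + 1] - xinf[i]);
    ed = edt[i] + f * (edt[i + 1] - edt[i]);
  }
};

struct Tables {
  // one activation (and optional inactivation) table per current
  std::vector<GateTable> act, inact;
  void build(const Model &M, double dt) {
    act.resize(M.cur.size());
    inact.resize(M.cur.size());
    for (size_t i = 0; i < M.cur.size(); ++i) {
      if (!M.cur[i].kca) act[i].build(M.cur[i].act, dt);
      if (M.cur[i].has_inact) inact[i].build(M.cur[i].inact, dt);
    }
  }
};

// Synaptic activation update with caching over the (mostly two-level)
// presynaptic waveform.
struct SynState {
  double last_vpre = 1e300, sinf = 0.0, edt = 1.0;
  inline double update(double s, double v_pre, const SynParams &P, double dt) {
    if (v_pre != last_vpre) {
      last_vpre = v_pre;
      sinf = syn_inf(v_pre, P);
      edt = std::exp(-dt / (P.tau * (1.0 - sinf)));
    }
    return sinf + (s - sinf) * edt;
  }
};

// One integration step over the ionic machinery; soma receives i_soma (pA).
// Returns max |dV| of this step (mV).
inline double ionic_step(const Model &M, const Tables &T, double *s,
                         double dt, double i_soma) {
  // gating (exponential Euler at the pre-step voltages)
  for (size_t i = 0; i < M.cur.size(); ++i) {
    const Current &C = M.cur[i];
    if (C.kca) continue;
    for (int c = 0; c < N_COMP; ++c) {
      if (C.m_idx[c] < 0) continue;
      double v = s[c], xi, ed;
      T.act[i].lookup(v, xi, ed);
      s[C.m_idx[c]] = xi + (s[C.m_idx[c]] - xi) * ed;
      if (C.has_inact) {
        T.inact[i].lookup(v, xi, ed);
        s[C.h_idx[c]] = xi + (s[C.h_idx[c]] - xi) * ed;
      }
    }
  }
  // membrane currents
  double I[N_COMP], Ica[N_COMP] = {0, 0, 0};
  for (int c = 0; c < N_COMP; ++c) I[c] = M.g_leak[c] * (M.e_leak - s[c]);
  I[0] += i_soma;
  for (size_t i = 0; i < M.cur.size(); ++i) {
    const Current &C = M.cur[i];
    for (int c = 0; c < N_COMP; ++c) {
      if (C.g[c] <= 0.0) continue;
      double a;
      if (C.kca) {
        double ca = s[M.ca_idx + c];
        a = ca / (ca + M.ca_khalf);
      } else {
        a = s[C.m_idx[c]];
      }
      double cur = C.g[c] * ipow(a, C.p) * (C.e_rev - s[c]);
      if (C.has_inact) cur *= s[C.h_idx[c]];
      I[c] += cur;
      if (C.ca_source && M.has_ca && cur > 0.0) Ica[c] += cur;
    }
  }
  I[0] += M.g_sx * (s[1] - s[0]) + M.g_sd * (s[2] - s[0]);
  I[1] += M.g_sx * (s[0] - s[1]);
  I[2] += M.g_sd * (s[0] - s[2]);
  double dvmax = 0.0;
  for (int c = 0; c < N_COMP; ++c) {
    double dv = dt * I[c] / M.cap[c];
    s[c] += dv;
    if (std::fabs(dv) > dvmax) dvmax = std::fabs(dv);
  }
  if (M.has_ca) {
    for (int c = 0; c < N_COMP; ++c) {
      double &ca = s[M.ca_idx + c];
      ca += dt * (M.ca_gain * Ica[c] - (ca - M.ca_rest) / M.ca_tau);
      if (ca < 0.0) ca = 0.0;
    }
  }
  return dvmax;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_init_state(List model) {
  Model M = parse_model(model);
  NumericVector s(M.n_state);
  double v0 = M.e_leak;
  for (int c = 0; c < N_COMP; ++c) s[c] = v0;
  for (const Current &C : M.cur) {
    if (C.kca) continue;
    for (int c = 0; c < N_COMP; ++c) {
      if (C.m_idx[c] >= 0) s[C.m_idx[c]] = gate_inf(v0, C.act);
      if (C.h_idx[c] >= 0) s[C.h_idx[c]] = gate_inf(v0, C.inact);
    }
  }
  if (M.has_ca)
    for (int c = 0; c < N_COMP; ++c) s[M.ca_idx + c] = M.ca_rest;
  s[M.se_idx] = 0.0; s[M.si_idx] = 0.0;
  return s;
}

// [[Rcpp::export]]
List cpp_settle(List model, double dt, double max_time, double tol) {
  Model M = parse_model(model);
  Tables T; T.build(M, dt);
  NumericVector st = cpp_init_state(model);
  std::vector<double> s(st.begin(), st.end());
  long n = static_cast<long>(std::llround(max_time / dt));
  bool converged = false, spiked = false;
  double t_end = max_time, vprev = s[0];
  for (long k = 0; k < n; ++k) {
    double dvmax = ionic_step(M, T, s.data(), dt, 0.0);
    if (s[0] >= -10.0 && vprev < -10.0) spiked = true;
    vprev = s[0];
    if (dvmax / dt < tol && k > 10) {
      converged = true;
      t_end = (k + 1) * dt;
      break;
    }
  }
  NumericVector out(s.begin(), s.end());
  return List::create(_["state"] = out, _["converged"] = converged,
                      _["spiked"] = spiked, _["time"] = t_end,
                      _["v_rest"] = s[0]);
}

// sweeps: list of lists with fields
//   len (ms), seg_t / seg_a (piecewise-constant injected current: amplitude
//   seg_a[j] holds until time seg_t[j], 0 afterwards), g_exc, g_inh (nS),
//   on_len (ms, synaptic drive window), win0 / win1 (analysis window, ms).
// wave_e / wave_i: presynaptic voltage waveforms sampled at wave_dt, replayed
// from sweep start over [0, on_len); baseline -100 mV outside.
// [[Rcpp::export]]
List cpp_simulate(List model, List sweeps, NumericVector wave_e,
                  NumericVector wave_i, double wave_dt, List syn, double dt,
                  double rec_dt, bool record, NumericVector state0,
                  double spike_thr, double refractory, double guard) {
  Model M = parse_model(model);
  Tables T; T.build(M, dt);
  SynParams SP = parse_syn(syn);
  std::vector<double> s(state0.begin(), state0.end());
  if (static_cast<int>(s.size()) != M.n_state)
    stop("state vector has wrong length for this model");

  int nsweep = sweeps.size();
  int rec_every = std::max(1, static_cast<int>(std::llround(rec_dt / dt)));
  List spike_out(nsweep);
  NumericMatrix summary(nsweep, 4);
  colnames(summary) = CharacterVector::create("v_base", "v_min", "v_steady",
                                              "v_end");
  List traces(record ? nsweep : 0);
  int diverged = 0;
  SynState se_cache, si_cache;
  int nw_e = wave_e.size(), nw_i = wave_i.size();

  for (int sw = 0; sw < nsweep && diverged == 0; ++sw) {
    List def = sweeps[sw];
    double len = as<double>(def["len"]);
    NumericVector seg_t = def["seg_t"], seg_a = def["seg_a"];
    double g_exc = as<double>(def["g_exc"]), g_inh = as<double>(def["g_inh"]);
    double on_len = as<double>(def["on_len"]);
    double win0 = as<double>(def["win0"]), win1 = as<double>(def["win1"]);
    long n = static_cast<long>(std::llround(len / dt));
    std::vector<double> spikes;
    std::vector<double> trace;
    if (record) trace.reserve(n / rec_every + 1);

    double base_sum = 0.0; long base_n = 0;
    double steady_sum = 0.0; long steady_n = 0;
    double vmin = 1e300;
    double base0 = std::max(0.0, win0 - 50.0);
    double steady0 = std::max(win0, win1 - 50.0);
    double last_spike = -1e300, vprev = s[0];
    int seg_ptr = 0, over = 0;

    for (long k = 0; k < n; ++k) {
      double t = k * dt;
      if (record && k % rec_every == 0) trace.push_back(s[0]);
      // injected current
      double inj = 0.0;
      while (seg_ptr < seg_t.size() && t >= seg_t[seg_ptr]) ++seg_ptr;
      if (seg_ptr < seg_t.size()) inj = seg_a[seg_ptr];
      // synaptic drive
      double isyn = 0.0;
      if (g_exc > 0.0 || g_inh > 0.0 || s[M.se_idx] > 1e-12 ||
          s[M.si_idx] > 1e-12) {
        double vpre_e = -100.0, vpre_i = -100.0;
        if (t < on_len) {
          long wi = static_cast<long>(t / wave_dt);
          if (nw_e > 0) vpre_e = wave_e[wi < nw_e ? wi : nw_e - 1];
          if (nw_i > 0) vpre_i = wave_i[wi < nw_i ? wi : nw_i - 1];
        }
        s[M.se_idx] = se_cache.update(s[M.se_idx], vpre_e, SP, dt);
        s[M.si_idx] = si_cache.update(s[M.si_idx], vpre_i, SP, dt);
        isyn = g_exc * s[M.se_idx] * (SP.e_exc - s[0]) +
               g_inh * s[M.si_idx] * (SP.e_inh - s[0]);
      }
      ionic_step(M, T, s.data(), dt, inj + isyn);
      double tn = t + dt;
      // spike detection at the soma
      if (s[0] >= spike_thr && vprev < spike_thr &&
          tn - last_spike >= refractory) {
        spikes.push_back(tn);
        last_spike = tn;
      }
      vprev = s[0];
      // analysis-window summaries
      if (tn > base0 && tn <= win0) { base_sum += s[0]; ++base_n; }
      if (tn > win0 && tn <= win1 && s[0] < vmin) vmin = s[0];
      if (tn > steady0 && tn <= win1) { steady_sum += s[0]; ++steady_n; }
      // divergence guard; a non-finite voltage aborts immediately
      bool out_of_range = false, non_finite = false;
      for (int c = 0; c < N_COMP; ++c) {
        if (!std::isfinite(s[c])) non_finite = true;
        if (std::fabs(s[c]) > guard) out_of_range = true;
      }
      if (non_finite) { diverged = sw + 1; break; }
      if (out_of_range) {
        if (++over > 50) { diverged = sw + 1; break; }
      } else over = 0;
    }
    spike_out[sw] = NumericVector(spikes.begin(), spikes.end());
    summary(sw, 0) = base_n ? base_sum / base_n : NA_REAL;
    summary(sw, 1) = vmin < 1e299 ? vmin : NA_REAL;
    summary(sw, 2) = steady_n ? steady_sum / steady_n : NA_REAL;
    summary(sw, 3) = s[0];
    if (record) traces[sw] = NumericVector(trace.begin(), trace.end());
  }

  NumericVector fin(s.begin(), s.end());
  return List::create(_["spikes"] = spike_out, _["summary"] = summary,
                      _["trace"] = traces, _["state"] = fin,
                      _["diverged"] = diverged);
}
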