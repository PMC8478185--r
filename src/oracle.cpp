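// Reference integrator: classical fixed-step 4th-order Runge-Kutta on the
// full continuous system (voltages, gating, Ca pool, synaptic activation),
// with direct transcendental evaluation of all rate functions. Used only as
// an independent cross-check of the production integrator.
#include "model.h"
using namespace Rcpp;
using namespace vclamp;

namespace {

struct Drive {
  double inj;            // injected somatic current, pA
  double vpre_e, vpre_i; // presynaptic voltages, mV
  double g_exc, g_inh;   // synaptic conductances, nS
};

void derivs(const Model &M, const SynParams &SP, const double *s,
            const Drive &D, double *ds) {
  double I[N_COMP], Ica[N_COMP] = {0, 0, 0};
  for (int c = 0; c < N_COMP; ++c) I[c] = M.g_leak[c] * (M.e_leak - s[c]);
  I[0] += D.inj;
  I[0] += D.g_exc * s[M.se_idx] * (SP.e_exc - s[0]) +
          D.g_inh * s[M.si_idx] * (SP.e_inh - s[0]);
  for (const Current &C : M.cur) {
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
  for (int c = 0; c < N_COMP; ++c) ds[c] = I[c] / M.cap[c];
  for (const Current &C : M.cur) {
    if (C.kca) continue;
    for (int c = 0; c < N_COMP; ++c) {
      if (C.m_idx[c] < 0) continue;
      double v = s[c];
      ds[C.m_idx[c]] =
          (gate_inf(v, C.act) - s[C.m_idx[c]]) / gate_tau(v, C.act);
      if (C.has_inact)
        ds[C.h_idx[c]] =
            (gate_inf(v, C.inact) - s[C.h_idx[c]]) / gate_tau(v, C.inact);
    }
  }
  if (M.has_ca) {
    for (int c = 0; c < N_COMP; ++c) {
      double ca = s[M.ca_idx + c];
      ds[M.ca_idx + c] = M.ca_gain * Ica[c] - (ca - M.ca_rest) / M.ca_tau;
    }
  }
  double se_inf = syn_inf(D.vpre_e, SP), si_inf = syn_inf(D.vpre_i, SP);
  ds[M.se_idx] = (se_inf - s[M.se_idx]) / (SP.tau * (1.0 - se_inf));
  ds[M.si_idx] = (si_inf - s[M.si_idx]) / (SP.tau * (1.0 - si_inf));
}

} // namespace

// Same sweep interface as cpp_simulate; returns spike times per sweep.
// [[Rcpp::export]]
List cpp_simulate_rk4(List model, List sweeps, NumericVector wave_e,
                      NumericVector wave_i, double wave_dt, List syn,
                      double dt, NumericVector state0, double spike_thr,
                      double refractory, double guard) {
  Model M = parse_model(model);
  SynParams SP = parse_syn(syn);
  std::vector<double> s(state0.begin(), state0.end());
  if (static_cast<int>(s.size()) != M.n_state)
    stop("state vector has wrong length for this model");
  int ns = M.n_state;
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  int nsweep = sweeps.size();
  List spike_out(nsweep);
  int diverged = 0;
  int nw_e = wave_e.size(), nw_i = wave_i.size();

  for (int sw = 0; sw < nsweep && diverged == 0; ++sw) {
    List def = sweeps[sw];
    double len = as<double>(def["len"]);
    NumericVector seg_t = def["seg_t"], seg_a = def["seg_a"];
    double g_exc = as<double>(def["g_exc"]), g_inh = as<double>(def["g_inh"]);
    double on_len = as<double>(def["on_len"]);
    long n = static_cast<long>(std::llround(len / dt));
    std::vector<double> spikes;
    double last_spike = -1e300, vprev = s[0];
    int over = 0;

    auto drive_at = [&](double t) {
      Drive D;
      D.g_exc = g_exc; D.g_inh = g_inh;
      D.inj = 0.0;
      for (int j = 0; j < seg_t.size(); ++j)
        if (t < seg_t[j]) { D.inj = seg_a[j]; break; }
      D.vpre_e = D.vpre_i = -100.0;
      if (t < on_len) {
        long wi = static_cast<long>(t / wave_dt);
        if (nw_e > 0) D.vpre_e = wave_e[wi < nw_e ? wi : nw_e - 1];
        if (nw_i > 0) D.vpre_i = wave_i[wi < nw_i ? wi : nw_i - 1];
      }
      return D;
    };

    for (long k = 0; k < n; ++k) {
      double t = k * dt;
      Drive D0 = drive_at(t), Dh = drive_at(t + dt / 2),
            D1 = drive_at(t + dt);
      derivs(M, SP, s.data(), D0, k1.data());
      for (int i = 0; i < ns; ++i) tmp[i] = s[i] + dt / 2 * k1[i];
      derivs(M, SP, tmp.data(), Dh, k2.data());
      for (int i = 0; i < ns; ++i) tmp[i] = s[i] + dt / 2 * k2[i];
      derivs(M, SP, tmp.data(), Dh, k3.data());
      for (int i = 0; i < ns; ++i) tmp[i] = s[i] + dt * k3[i];
      derivs(M, SP, tmp.data(), D1, k4.data());
      for (int i = 0; i < ns; ++i)
        s[i] += dt / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      double tn = t + dt;
      if (s[0] >= spike_thr && vprev < spike_thr &&
          tn - last_spike >= refractory) {
        spikes.push_back(tn);
        last_spike = tn;
      }
      vprev = s[0];
      bool oor = false, non_finite = false;
      for (int c = 0; c < N_COMP; ++c) {
        if (!std::isfinite(s[c])) non_finite = true;
        if (std::fabs(s[c]) > guard) oor = true;
      }
      if (non_finite) { diverged = sw + 1; break; }
      if (oor) {
        if (++over > 200) { diverged = sw + 1; break; }
      } else over = 0;
    }
    spike_out[sw] = NumericVector(spikes.begin(), spikes.end());
  }
  NumericVector fin(s.begin(), s.end());
  return List::create(_["spikes"] = spike_out, _["state"] = fin,
                      _["diverged"] = diverged);
}
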