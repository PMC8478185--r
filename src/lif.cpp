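// Leaky integrate-and-fire control model: passive RC subthreshold dynamics,
// threshold/reset spiking with an absolute refractory period, driven by the
// same current-step and synaptic-bombardment sweep definitions as the
// conductance-based models.
#include "model.h"
using namespace Rcpp;
using namespace vclamp;

// [[Rcpp::export]]
List cpp_lif_simulate(List params, List sweeps, NumericVector wave_e,
                      NumericVector wave_i, double wave_dt, List syn,
                      double dt) {
  double cap = as<double>(params["cap"]);
  double g_l = as<double>(params["g_leak"]);
  double e_l = as<double>(params["e_leak"]);
  double v_th = as<double>(params["v_th"]);
  double v_reset = as<double>(params["v_reset"]);
  double t_ref = as<double>(params["t_ref"]);
  SynParams SP = parse_syn(syn);

  double v = e_l, se = 0.0, si = 0.0;
  double ref_until = -1e300;
  int nsweep = sweeps.size();
  List spike_out(nsweep);
  NumericVector v_end(nsweep);
  int nw_e = wave_e.size(), nw_i = wave_i.size();
  double last_vpre_e = 1e300, last_vpre_i = 1e300;
  double se_inf = 0.0, si_inf = 0.0, se_edt = 1.0, si_edt = 1.0;
  double t_abs = 0.0;

  for (int sw = 0; sw < nsweep; ++sw) {
    List def = sweeps[sw];
    double len = as<double>(def["len"]);
    NumericVector seg_t = def["seg_t"], seg_a = def["seg_a"];
    double g_exc = as<double>(def["g_exc"]), g_inh = as<double>(def["g_inh"]);
    double on_len = as<double>(def["on_len"]);
    long n = static_cast<long>(std::llround(len / dt));
    std::vector<double> spikes;
    int seg_ptr = 0;

    for (long k = 0; k < n; ++k) {
      double t = k * dt;
      double inj = 0.0;
      while (seg_ptr < seg_t.size() && t >= seg_t[seg_ptr]) ++seg_ptr;
      if (seg_ptr < seg_t.size()) inj = seg_a[seg_ptr];
      double vpre_e = -100.0, vpre_i = -100.0;
      if (t < on_len) {
        long wi = static_cast<long>(t / wave_dt);
        if (nw_e > 0) vpre_e = wave_e[wi < nw_e ? wi : nw_e - 1];
        if (nw_i > 0) vpre_i = wave_i[wi < nw_i ? wi : nw_i - 1];
      }
      if (vpre_e != last_vpre_e) {
        last_vpre_e = vpre_e;
        se_inf = syn_inf(vpre_e, SP);
        se_edt = std::exp(-dt / (SP.tau * (1.0 - se_inf)));
      }
      if (vpre_i != last_vpre_i) {
        last_vpre_i = vpre_i;
        si_inf = syn_inf(vpre_i, SP);
        si_edt = std::exp(-dt / (SP.tau * (1.0 - si_inf)));
      }
      se = se_inf + (se - se_inf) * se_edt;
      si = si_inf + (si - si_inf) * si_edt;
      double tn_abs = t_abs + (k + 1) * dt;
      if (tn_abs < ref_until) {
        v = v_reset;
        continue;
      }
      double isyn = g_exc * se * (SP.e_exc - v) + g_inh * si * (SP.e_inh - v);
      v += dt * (g_l * (e_l - v) + inj + isyn) / cap;
      if (v >= v_th) {
        spikes.push_back(t + dt);
        v = v_reset;
        ref_until = tn_abs + t_ref;
      }
    }
    spike_out[sw] = NumericVector(spikes.begin(), spikes.end());
    v_end[sw] = v;
    t_abs += len;
  }
  return List::create(_["spikes"] = spike_out, _["v_end"] = v_end);
}
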