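#include <Rcpp.h>
using namespace Rcpp;

// Clocked forward simulation of one trial through the three-layer
// spiking network: input spikes -> hidden LIF layer (with presynaptic
// Tsodyks-Markram STP on both synapse banks) -> output LIF layer.
//
// When `learn` is true and a teacher spike matrix is supplied, the
// kernel also accumulates the teacher-driven STDP adjustment for the
// hidden->output synapses, delta[j,k] += (teach_k(t) - out_k(t)) *
// trace_j(t), where trace_j is the exponential presynaptic spike trace
// with time constant tau_trace, and records which input->hidden
// synapses were "active" (presynaptic trace above `active_min` at a
// postsynaptic hidden spike), the mask the self-backpropagation step
// mirrors output adjustments onto.
//
// Synapses inject charge: a presynaptic spike adds r_m * w * stp_efficacy to
// the postsynaptic membrane potential; the membrane otherwise decays
// toward v_rest with time constant tau_m (forward Euler).
// [[Rcpp::export]]
List sim_trial_cpp(const IntegerMatrix& spikes_in,   // n_in x T
                   const NumericMatrix& W_ih,        // n_in x n_hidden
                   const NumericMatrix& W_ho,        // n_hidden x n_out
                   const NumericVector& vth_hidden,  // per-neuron thresholds
                   const List& lif,                  // hidden: tau_m, v_rest, v_reset, v_th, t_ref, r_m
                   const List& lif_out,              // output layer LIF parameters
                   const List& stp,                  // U, tau_f, tau_d
                   double dt,
                   double tau_trace,
                   const IntegerMatrix& teach,       // n_out x T, or 0 x 0
                   bool learn,
                   double active_min) {
  const int n_in = spikes_in.nrow();
  const int T = spikes_in.ncol();
  const int n_h = W_ih.ncol();
  const int n_out = W_ho.ncol();
  const bool has_teach = teach.nrow() == n_out && teach.ncol() == T;

  const double tau_m = as<double>(lif["tau_m"]);
  const double v_rest = as<double>(lif["v_rest"]);
  const double v_reset = as<double>(lif["v_reset"]);
  const double t_ref = as<double>(lif["t_ref"]);
  const double r_m = as<double>(lif["r_m"]);
  const int ref_steps = (int)std::ceil(t_ref / dt);
  const double leak = dt / tau_m;
  const double vo_rest = as<double>(lif_out["v_rest"]);
  const double vo_reset = as<double>(lif_out["v_reset"]);
  const double v_th_out = as<double>(lif_out["v_th"]);
  const double ro_m = as<double>(lif_out["r_m"]);
  const int ref_steps_out = (int)std::ceil(as<double>(lif_out["t_ref"]) / dt);
  const double leak_out = dt / as<double>(lif_out["tau_m"]);

  const double U = as<double>(stp["U"]);
  const double df_u = std::exp(-dt / as<double>(stp["tau_f"]));
  const double df_r = std::exp(-dt / as<double>(stp["tau_d"]));
  const double df_tr = std::exp(-dt / tau_trace);

  std::vector<double> u_in(n_in, 0.0), R_in(n_in, 1.0);
  std::vector<double> u_h(n_h, 0.0), R_h(n_h, 1.0);
  std::vector<double> v_h(n_h, v_rest), v_o(n_out, vo_rest);
  std::vector<int> ref_h(n_h, 0), ref_o(n_out, 0);
  std::vector<double> tr_in(n_in, 0.0), tr_h(n_h, 0.0);
  std::vector<double> inj_h(n_h), inj_o(n_out);
  std::vector<int> s_h(n_h);

  NumericVector out_counts(n_out), hidden_counts(n_h);
  NumericMatrix delta_ho(n_h, n_out);
  IntegerMatrix active(n_in, n_h);
  NumericMatrix out_spikes(n_out, T);

  for (int t = 0; t < T; ++t) {
    // --- input STP decay + spikes -> hidden injection
    std::fill(inj_h.begin(), inj_h.end(), 0.0);
    for (int i = 0; i < n_in; ++i) {
      u_in[i] *= df_u;
      R_in[i] = 1.0 - (1.0 - R_in[i]) * df_r;
      tr_in[i] *= df_tr;
      if (spikes_in(i, t)) {
        u_in[i] += U * (1.0 - u_in[i]);
        const double eff = u_in[i] * R_in[i];
        R_in[i] *= (1.0 - u_in[i]);
        tr_in[i] += 1.0;
        for (int j = 0; j < n_h; ++j) inj_h[j] += r_m * W_ih(i, j) * eff;
      }
    }
    // --- hidden LIF
    std::fill(inj_o.begin(), inj_o.end(), 0.0);
    for (int j = 0; j < n_h; ++j) {
      u_h[j] *= df_u;
      R_h[j] = 1.0 - (1.0 - R_h[j]) * df_r;
      tr_h[j] *= df_tr;
      s_h[j] = 0;
      if (ref_h[j] > 0) { --ref_h[j]; continue; }
      v_h[j] += -(v_h[j] - v_rest) * leak + inj_h[j];
      if (v_h[j] >= vth_hidden[j]) {
        s_h[j] = 1;
        v_h[j] = v_reset;
        ref_h[j] = ref_steps;
        hidden_counts[j] += 1.0;
        tr_h[j] += 1.0;
        u_h[j] += U * (1.0 - u_h[j]);
        const double eff = u_h[j] * R_h[j];
        R_h[j] *= (1.0 - u_h[j]);
        for (int k = 0; k < n_out; ++k) inj_o[k] += ro_m * W_ho(j, k) * eff;
        if (learn) {
          for (int i = 0; i < n_in; ++i) {
            if (tr_in[i] >= active_min) active(i, j) = 1;
          }
        }
      }
    }
    // --- output LIF
    for (int k = 0; k < n_out; ++k) {
      int s_out = 0;
      if (ref_o[k] > 0) {
        --ref_o[k];
      } else {
        v_o[k] += -(v_o[k] - vo_rest) * leak_out + inj_o[k];
        if (v_o[k] >= v_th_out) {
          s_out = 1;
          v_o[k] = vo_reset;
          ref_o[k] = ref_steps_out;
          out_counts[k] += 1.0;
        }
      }
      out_spikes(k, t) = s_out;
      if (learn && has_teach) {
        const int e = teach(k, t) - s_out;
        if (e != 0) {
          for (int j = 0; j < n_h; ++j) delta_ho(j, k) += e * tr_h[j];
        }
      }
    }
  }

  return List::create(_["out_counts"] = out_counts,
                      _["hidden_counts"] = hidden_counts,
                      _["delta_ho"] = delta_ho,
                      _["active"] = active,
                      _["out_spikes"] = out_spikes);
}
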