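#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time MGC network engine.
//
// All synapses of a pathway share one decay constant, so per-target pathway
// currents can be aggregated into a single exponentially-decaying accumulator:
//   I_{k+1} = I_k * alpha_syn + b * sum_j w[.,j] * spike_j(k)
// with alpha_syn = exp(-delta/tau_syn) = 1 - delta/tau_corrected (exact
// integration). Somata then update as
//   v_{k+1} = v_k * alpha_m + (delta/c_m) * I_total
// followed by threshold test and same-step reset to v_ahp.
//
// Spikes of step k reach synapses at step k+1 (one iteration per clock).
//
// Weight matrices are signed: excitatory pathways non-negative, inhibitory
// non-positive. STDP (ORN->LN, LN->LN only) adapts the *magnitude* of each
// weight, clipped to [max(0, w_min), w_max] so a synapse never changes sign.

static inline double stdp_dw(double dt, double dwp, double dwm,
                             double tp, double tm) {
  if (dt <= 0.0)
    return dwp * (tp / (tm + tp)) * std::exp(-std::fabs(dt) / tp);
  return -dwm * (1.0 - tm / (tm + tp)) * std::exp(-dt / tm);
}

// [[Rcpp::export]]
List mgc_sim_core(NumericMatrix W_ol, NumericMatrix W_op,
                  NumericMatrix W_ll, NumericMatrix W_lp,
                  NumericMatrix W_pp,
                  LogicalMatrix A_ll,
                  NumericMatrix input,      // n_steps x n_orn soma current
                  double delta,
                  double tau_orn, double tau_ln, double tau_pn,
                  double tau_e, double tau_i,
                  double v_theta, double v_ahp, double c_m,
                  NumericVector b,          // b_ol, b_op, b_ll, b_lp, b_pp
                  double noise_sigma,
                  bool stdp_on,
                  double dw_plus, double dw_minus,
                  double tau_plus, double tau_minus,
                  double w_min, double w_max,
                  bool record_v) {
  const int n_steps = input.nrow();
  const int n_orn = W_ol.ncol();
  const int n_ln  = W_ol.nrow();
  const int n_pn  = W_op.nrow();
  const int n_tot = n_orn + n_ln + n_pn;

  const double a_orn = std::exp(-delta / tau_orn);
  const double a_ln  = std::exp(-delta / tau_ln);
  const double a_pn  = std::exp(-delta / tau_pn);
  const double a_e   = std::exp(-delta / tau_e);
  const double a_i   = std::exp(-delta / tau_i);
  const double g     = delta / c_m;
  const double b_ol = b[0], b_op = b[1], b_ll = b[2], b_lp = b[3], b_pp = b[4];
  const double mlo = std::max(0.0, w_min), mhi = w_max;

  // copies: STDP mutates weights
  NumericMatrix Wol(clone(W_ol)), Wll(clone(W_ll));

  std::vector<double> v_orn(n_orn, 0.0), v_ln(n_ln, 0.0), v_pn(n_pn, 0.0);
  std::vector<double> I_ol(n_ln, 0.0), I_ll(n_ln, 0.0);
  std::vector<double> I_op(n_pn, 0.0), I_lp(n_pn, 0.0), I_pp(n_pn, 0.0);
  std::vector<int> sp_orn_prev, sp_ln_prev, sp_pn_prev;
  std::vector<int> sp_orn, sp_ln, sp_pn;
  std::vector<int> last_orn(n_orn, -1), last_ln(n_ln, -1);
  std::vector<char> ln_spiked_now(n_ln, 0), orn_spiked_now(n_orn, 0);

  std::vector<int> out_neuron, out_step;
  NumericMatrix Vrec = record_v ? NumericMatrix(n_steps, n_tot)
                                : NumericMatrix(0, 0);
  double abs_change = 0.0;

  RNGScope scope;

  for (int k = 0; k < n_steps; ++k) {
    // ---- synapses: decay, then inject pulses from step k-1 spikes
    for (int i = 0; i < n_ln; ++i) { I_ol[i] *= a_e; I_ll[i] *= a_i; }
    for (int i = 0; i < n_pn; ++i) { I_op[i] *= a_e; I_lp[i] *= a_i; I_pp[i] *= a_e; }
    for (int j : sp_orn_prev) {
      for (int i = 0; i < n_ln; ++i) I_ol[i] += b_ol * Wol(i, j);
      for (int i = 0; i < n_pn; ++i) I_op[i] += b_op * W_op(i, j);
    }
    for (int j : sp_ln_prev) {
      for (int i = 0; i < n_ln; ++i) I_ll[i] += b_ll * Wll(i, j);
      for (int i = 0; i < n_pn; ++i) I_lp[i] += b_lp * W_lp(i, j);
    }
    for (int j : sp_pn_prev) {
      for (int i = 0; i < n_pn; ++i) I_pp[i] += b_pp * W_pp(i, j);
    }

    // ---- somata
    sp_orn.clear(); sp_ln.clear(); sp_pn.clear();
    for (int j = 0; j < n_orn; ++j) {
      double drive = input(k, j);
      if (noise_sigma > 0.0) drive += noise_sigma * R::norm_rand();
      v_orn[j] = v_orn[j] * a_orn + g * drive;
      if (record_v) Vrec(k, j) = v_orn[j];
      if (v_orn[j] >= v_theta) {
        v_orn[j] = v_ahp; sp_orn.push_back(j);
        if (record_v) Vrec(k, j) = v_ahp;
      }
    }
    for (int i = 0; i < n_ln; ++i) {
      v_ln[i] = v_ln[i] * a_ln + g * (I_ol[i] + I_ll[i]);
      if (record_v) Vrec(k, n_orn + i) = v_ln[i];
      if (v_ln[i] >= v_theta) {
        v_ln[i] = v_ahp; sp_ln.push_back(i);
        if (record_v) Vrec(k, n_orn + i) = v_ahp;
      }
    }
    for (int i = 0; i < n_pn; ++i) {
      v_pn[i] = v_pn[i] * a_pn + g * (I_op[i] + I_lp[i] + I_pp[i]);
      if (record_v) Vrec(k, n_orn + n_ln + i) = v_pn[i];
      if (v_pn[i] >= v_theta) {
        v_pn[i] = v_ahp; sp_pn.push_back(i);
        if (record_v) Vrec(k, n_orn + n_ln + i) = v_ahp;
      }
    }

    // ---- STDP on ORN->LN and LN->LN (nearest-spike pairing)
    if (stdp_on) {
      for (int j : sp_orn) orn_spiked_now[j] = 1;
      for (int i : sp_ln) ln_spiked_now[i] = 1;

      // potentiation: post LN spike at k pairs with most recent pre spike
      for (int i : sp_ln) {
        for (int j = 0; j < n_orn; ++j) {
          int tp = orn_spiked_now[j] ? k : last_orn[j];
          if (tp < 0) continue;
          double dw = stdp_dw((tp - k) * delta, dw_plus, dw_minus,
                              tau_plus, tau_minus);
          double m = Wol(i, j), m2 = std::min(mhi, std::max(mlo, m + dw));
          abs_change += std::fabs(m2 - m); Wol(i, j) = m2;
        }
        for (int j = 0; j < n_ln; ++j) {
          if (j == i || !A_ll(i, j)) continue;
          int tp = ln_spiked_now[j] ? k : last_ln[j];
          if (tp < 0) continue;
          double dw = stdp_dw((tp - k) * delta, dw_plus, dw_minus,
                              tau_plus, tau_minus);
          double m = -Wll(i, j), m2 = std::min(mhi, std::max(mlo, m + dw));
          abs_change += std::fabs(m2 - m); Wll(i, j) = -m2;
        }
      }
      // depression: pre spike at k pairs with most recent *earlier* post spike
      for (int j : sp_orn) {
        for (int i = 0; i < n_ln; ++i) {
          if (ln_spiked_now[i] || last_ln[i] < 0) continue;
          double dw = stdp_dw((k - last_ln[i]) * delta, dw_plus, dw_minus,
                              tau_plus, tau_minus);
          double m = Wol(i, j), m2 = std::min(mhi, std::max(mlo, m + dw));
          abs_change += std::fabs(m2 - m); Wol(i, j) = m2;
        }
      }
      for (int j : sp_ln) {
        for (int i = 0; i < n_ln; ++i) {
          if (i == j || !A_ll(i, j) || ln_spiked_now[i] || last_ln[i] < 0)
            continue;
          double dw = stdp_dw((k - last_ln[i]) * delta, dw_plus, dw_minus,
                              tau_plus, tau_minus);
          double m = -Wll(i, j), m2 = std::min(mhi, std::max(mlo, m + dw));
          abs_change += std::fabs(m2 - m); Wll(i, j) = -m2;
        }
      }
      for (int j : sp_orn) { orn_spiked_now[j] = 0; last_orn[j] = k; }
      for (int i : sp_ln) { ln_spiked_now[i] = 0; last_ln[i] = k; }
    }

    // ---- record
    for (int j : sp_orn) { out_neuron.push_back(j); out_step.push_back(k); }
    for (int i : sp_ln) { out_neuron.push_back(n_orn + i); out_step.push_back(k); }
    for (int i : sp_pn) { out_neuron.push_back(n_orn + n_ln + i); out_step.push_back(k); }
    std::swap(sp_orn_prev, sp_orn);
    std::swap(sp_ln_prev, sp_ln);
    std::swap(sp_pn_prev, sp_pn);
  }

  List out = List::create(
    _["neuron"] = wrap(out_neuron),   // 0-based; ORN, then LN, then PN
    _["step"] = wrap(out_step),       // 0-based
    _["W_ol"] = Wol, _["W_ll"] = Wll,
    _["abs_change"] = abs_change);
  if (record_v) out["v"] = Vrec;
  return out;
}

// Single LIF soma driven by an arbitrary current series (exact integration).
// [[Rcpp::export]]
List lif_run_core(NumericVector current, double delta, double tau_m,
                  double v_theta, double v_ahp, double c_m) {
  const int n = current.size();
  const double a = std::exp(-delta / tau_m), g = delta / c_m;
  double v = 0.0;
  NumericVector vout(n);
  std::vector<int> spikes;
  for (int k = 0; k < n; ++k) {
    v = v * a + g * current[k];
    if (v >= v_theta) { v = v_ahp; spikes.push_back(k); }
    vout[k] = v;
  }
  return List::create(_["v"] = vout, _["spike_steps"] = wrap(spikes));
}
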