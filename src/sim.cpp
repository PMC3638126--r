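#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire network stepper with conductance synapses and
// (optionally) reward-gated STDP.
//
// Update scheme per step of length dt (ms), advancing from t to t_new:
//   1. excitatory conductances decay by exp(-dt / tau_syn);
//   2. external Poisson drives deliver at most one event per drive per
//      neuron per step (probability rate * dt), incrementing g by the
//      drive weight; constant currents i_ext are applied continuously;
//   3. membrane potentials advance by the exponential-Euler solution of
//      C dV/dt = g_leak (E_L - V) + g (E_e - V); refractory neurons hold
//      at the reset potential;
//   4. neurons at or above threshold fire at t_new: reset, refractory,
//      spike logged;
//   5. if plasticity is on, each new spike pairs as a postsynaptic partner
//      first (potentiation pass over spiking neurons in ascending id), then
//      each spiking neuron propagates its outgoing synapses (conductance
//      increments land on the next step) and pairs as a presynaptic
//      partner (depression pass). Pairing is nearest-neighbor by default:
//      a new spike pairs once with the most recent partner spike inside
//      the window; the all-pairs variant pairs with every partner spike
//      inside the window. A pre and post spike in the same step pair on
//      the depression branch (dt = 0). Weight changes are
//      delta(dt)/100 * w_max, clamped to [0, w_max] after each pairing.

// [[Rcpp::export]]
List sim_run_cpp(NumericVector V_in, NumericVector g_in,
                 NumericVector refrac_in,
                 IntegerVector syn_pre, IntegerVector syn_post,
                 NumericVector syn_w_in, IntegerVector syn_potentiating,
                 IntegerVector syn_proj,
                 List neuron_params, List stdp_params,
                 NumericMatrix drive_rate, NumericVector drive_w,
                 IntegerVector drive_type, NumericVector drive_delay_lo,
                 NumericVector drive_delay_hi, IntegerVector drive_volley_id,
                 NumericVector i_ext,
                 double t0, double duration, double dt,
                 bool plasticity, bool all_pairs, bool depression_only,
                 List spike_hist,
                 double record_every, int n_proj) {
  // work on copies: callers keep snapshots of state vectors
  NumericVector V = clone(V_in);
  NumericVector g = clone(g_in);
  NumericVector refrac_until = clone(refrac_in);
  NumericVector syn_w = clone(syn_w_in);

  const int n = V.size();
  const int n_syn = syn_pre.size();
  const int n_drives = drive_rate.nrow();

  const double tau_m = as<double>(neuron_params["membrane_tau"]);
  const double e_l = as<double>(neuron_params["rest_potential"]);
  const double v_th = as<double>(neuron_params["threshold"]);
  const double v_reset = as<double>(neuron_params["reset_potential"]);
  const double t_ref = as<double>(neuron_params["refractory"]);
  const double e_e = as<double>(neuron_params["excitatory_reversal"]);
  const double tau_syn = as<double>(neuron_params["synapse_tau"]);
  const double g_leak = as<double>(neuron_params["leak_conductance"]);
  const double cm = g_leak * tau_m; // nF when g in uS, tau in ms

  const double a_plus = as<double>(stdp_params["a_plus"]);
  const double a_minus = as<double>(stdp_params["a_minus"]);
  const double tau_p = as<double>(stdp_params["tau_plus"]);
  const double tau_d = as<double>(stdp_params["tau_minus"]);
  const double win_p = as<double>(stdp_params["window_plus"]);
  const double win_d = as<double>(stdp_params["window_minus"]);
  const double w_max = as<double>(stdp_params["w_max"]);
  const double dscale = w_max / 100.0; // A is percent of max conductance
  const double win_keep = std::max(win_p, win_d);

  const double g_decay = std::exp(-dt / tau_syn);

  // adjacency
  std::vector<std::vector<int> > out_syn(n), in_syn(n);
  for (int s = 0; s < n_syn; ++s) {
    out_syn[syn_pre[s] - 1].push_back(s);
    in_syn[syn_post[s] - 1].push_back(s);
  }

  std::vector<std::vector<double> > hist(n);
  for (int i = 0; i < n; ++i) {
    NumericVector h = spike_hist[i];
    hist[i].assign(h.begin(), h.end());
  }

  std::vector<double> spk_t;
  std::vector<int> spk_n;
  std::vector<double> trace; // rows: time, then n_proj means
  std::vector<int> proj_count(n_proj, 0);
  for (int s = 0; s < n_syn; ++s) proj_count[syn_proj[s] - 1]++;

  // ring buffer of delayed conductance deliveries (volley drives)
  double max_delay = 0.0;
  for (int d = 0; d < n_drives; ++d) {
    if (drive_type[d] >= 1 && drive_delay_hi[d] > max_delay) {
      max_delay = drive_delay_hi[d];
    }
  }
  const int n_slots = (int)std::ceil(max_delay / dt) + 2;
  std::vector<std::vector<double> > pending(n_slots, std::vector<double>(n, 0.0));
  int slot = 0;

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int rec_steps = record_every > 0 ? (int)std::floor(record_every / dt + 0.5) : 0;
  std::vector<int> spiking;
  std::vector<char> is_spiking(n, 0);
  std::vector<char> volley_event(n_drives, 0);
  // periodic volley drives (type 2): first event half an interval in
  std::vector<double> next_event(n_drives, 0.0);
  for (int d = 0; d < n_drives; ++d) {
    if (drive_type[d] == 2) {
      double r_shared = 0.0;
      for (int i = 0; i < n; ++i) {
        if (drive_rate(d, i) > r_shared) r_shared = drive_rate(d, i);
      }
      next_event[d] = r_shared > 0.0 ? t0 + 500.0 / r_shared : R_PosInf;
    }
  }

  for (int stp = 0; stp < n_steps; ++stp) {
    const double t_new = t0 + (stp + 1) * dt;

    // 1-2: conductance decay + external events
    for (int i = 0; i < n; ++i) g[i] *= g_decay;
    {
      std::vector<double>& due = pending[slot];
      for (int i = 0; i < n; ++i) {
        if (due[i] != 0.0) { g[i] += due[i]; due[i] = 0.0; }
      }
    }
    for (int d = 0; d < n_drives; ++d) {
      const double w = drive_w[d];
      if (drive_type[d] == 0) { // independent Poisson per neuron
        for (int i = 0; i < n; ++i) {
          const double r = drive_rate(d, i);
          if (r > 0.0 && unif_rand() < r * dt * 1e-3) g[i] += w;
        }
      } else { // shared volley: one event stream, jittered per-neuron delivery
        // drives with the same positive volley id share one event stream
        bool event;
        const int vid = drive_volley_id[d];
        int owner = d;
        if (vid > 0) {
          for (int d2 = 0; d2 < d; ++d2) {
            if (drive_type[d2] >= 1 && drive_volley_id[d2] == vid) { owner = d2; break; }
          }
        }
        if (owner == d) {
          double r_shared = 0.0;
          for (int i = 0; i < n; ++i) {
            if (drive_rate(d, i) > r_shared) r_shared = drive_rate(d, i);
          }
          if (drive_type[d] == 2) { // periodic
            event = r_shared > 0.0 && t_new >= next_event[d];
            if (event) next_event[d] += 1000.0 / r_shared;
          } else { // Poisson stream
            event = (r_shared > 0.0 && unif_rand() < r_shared * dt * 1e-3);
          }
          volley_event[d] = event ? 1 : 0;
        } else {
          event = volley_event[owner] == 1;
          volley_event[d] = event ? 1 : 0;
        }
        if (event) {
          const double lo = drive_delay_lo[d], hi = drive_delay_hi[d];
          for (int i = 0; i < n; ++i) {
            if (drive_rate(d, i) <= 0.0) continue;
            const double delay = lo + (hi - lo) * unif_rand();
            int ahead = (int)std::floor(delay / dt + 0.5);
            if (ahead >= n_slots) ahead = n_slots - 1;
            if (ahead <= 0) g[i] += w;
            else pending[(slot + ahead) % n_slots][i] += w;
          }
        }
      }
    }
    slot = (slot + 1) % n_slots;

    // 3: membrane update
    spiking.clear();
    for (int i = 0; i < n; ++i) {
      if (t_new < refrac_until[i]) { V[i] = v_reset; continue; }
      const double g_tot = g_leak + g[i];
      const double v_inf = (g_leak * e_l + g[i] * e_e + i_ext[i]) / g_tot;
      const double tau_eff = cm / g_tot;
      V[i] = v_inf + (V[i] - v_inf) * std::exp(-dt / tau_eff);
      if (V[i] >= v_th) spiking.push_back(i);
    }

    if (!spiking.empty()) {
      for (size_t k = 0; k < spiking.size(); ++k) {
        const int i = spiking[k];
        V[i] = v_reset;
        refrac_until[i] = t_new + t_ref;
        spk_t.push_back(t_new);
        spk_n.push_back(i + 1);
        is_spiking[i] = 1;
      }

      if (plasticity) {
        // potentiation pass: new spikes as postsynaptic partners
        for (size_t k = 0; k < spiking.size(); ++k) {
          const int q = spiking[k];
          const std::vector<int>& ins = in_syn[q];
          for (size_t a = 0; a < ins.size(); ++a) {
            const int s = ins[a];
            if (depression_only || !syn_potentiating[s]) continue;
            const std::vector<double>& hp = hist[syn_pre[s] - 1];
            for (int b = (int)hp.size() - 1; b >= 0; --b) {
              const double lag = t_new - hp[b]; // > 0: pre strictly earlier
              if (lag > win_p) break;
              syn_w[s] += dscale * a_plus * std::exp(-lag / tau_p);
              if (syn_w[s] > w_max) syn_w[s] = w_max;
              if (!all_pairs) break;
            }
          }
        }
        // depression pass: new spikes as presynaptic partners
        for (size_t k = 0; k < spiking.size(); ++k) {
          const int p = spiking[k];
          const std::vector<int>& outs = out_syn[p];
          for (size_t a = 0; a < outs.size(); ++a) {
            const int s = outs[a];
            const int q = syn_post[s] - 1;
            bool paired = false;
            if (is_spiking[q]) { // simultaneous spike: dt = 0
              syn_w[s] -= dscale * a_minus;
              if (syn_w[s] < 0.0) syn_w[s] = 0.0;
              paired = true;
            }
            if (!paired || all_pairs) {
              const std::vector<double>& hq = hist[q];
              for (int b = (int)hq.size() - 1; b >= 0; --b) {
                const double lag = t_new - hq[b]; // >= 0: post earlier
                if (lag > win_d) break;
                syn_w[s] -= dscale * a_minus * std::exp(-lag / tau_d);
                if (syn_w[s] < 0.0) syn_w[s] = 0.0;
                if (!all_pairs) break;
              }
            }
          }
        }
      }

      // propagation (conductance increments take effect next step)
      for (size_t k = 0; k < spiking.size(); ++k) {
        const int p = spiking[k];
        const std::vector<int>& outs = out_syn[p];
        for (size_t a = 0; a < outs.size(); ++a) {
          g[syn_post[outs[a]] - 1] += syn_w[outs[a]];
        }
      }

      // history bookkeeping
      for (size_t k = 0; k < spiking.size(); ++k) {
        const int i = spiking[k];
        is_spiking[i] = 0;
        hist[i].push_back(t_new);
      }
      for (size_t k = 0; k < spiking.size(); ++k) {
        std::vector<double>& h = hist[spiking[k]];
        size_t drop = 0;
        while (drop < h.size() && h[drop] < t_new - win_keep - dt) ++drop;
        if (drop > 0) h.erase(h.begin(), h.begin() + drop);
      }
    }

    if (rec_steps > 0 && ((stp + 1) % rec_steps == 0)) {
      trace.push_back(t_new);
      std::vector<double> acc(n_proj, 0.0);
      for (int s = 0; s < n_syn; ++s) acc[syn_proj[s] - 1] += syn_w[s];
      for (int pj = 0; pj < n_proj; ++pj) {
        trace.push_back(proj_count[pj] > 0 ? acc[pj] / proj_count[pj] : NA_REAL);
      }
    }
  }

  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(V[i]) || !std::isfinite(g[i])) {
      stop("Non-finite state for neuron %d at end of interval.", i + 1);
    }
  }

  List hist_out(n);
  for (int i = 0; i < n; ++i) hist_out[i] = NumericVector(hist[i].begin(), hist[i].end());

  NumericMatrix trace_mat(0, 0);
  if (rec_steps > 0 && !trace.empty()) {
    const int ncol = 1 + n_proj;
    const int nrow = (int)trace.size() / ncol;
    trace_mat = NumericMatrix(nrow, ncol);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < ncol; ++c)
        trace_mat(r, c) = trace[r * ncol + c];
  }

  return List::create(
    _["V"] = V, _["g"] = g, _["refrac_until"] = refrac_until,
    _["syn_w"] = syn_w,
    _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["spike_n"] = IntegerVector(spk_n.begin(), spk_n.end()),
    _["spike_hist"] = hist_out,
    _["weight_trace"] = trace_mat
  );
}
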