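#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven LIF network integrator.
//
// Per step, in fixed order: decay synaptic currents; deliver events due this
// step (external drive, queued fast synaptic events, queued slow rebound
// events); advance every membrane with the exact-exponential update for the
// current held constant over the step; detect threshold crossings, reset and
// start refractoriness; enqueue downstream events at spike step + delay.
// All randomness (Bernoulli release) is drawn from R's RNG so a set.seed()
// before the call makes the run bit-reproducible. Events within one step are
// processed in (pre, post) order, so ties are deterministic.
//
// Synaptic currents are three exponential accumulators per neuron: fast
// excitatory, fast inhibitory, slow rebound. A rebound-flagged edge delivers
// its fast inhibitory event through the usual Bernoulli draw and, in
// addition, always schedules exactly one slow excitatory kernel at
// arrival + t_delay (the relay stands in for the intermediate population
// with non-probabilistic synapses).

struct Ev { int post; double w; bool slow; };

// [[Rcpp::export]]
List engine_run_cpp(int n_neurons,
                    NumericVector E_L, NumericVector theta,
                    NumericVector tau_m, NumericVector C_m,
                    NumericVector V_reset, IntegerVector t_ref_steps,
                    double tau_syn_exc, double tau_syn_inh,
                    IntegerVector edge_pre, IntegerVector edge_post,
                    NumericVector edge_w, IntegerVector edge_delay_steps,
                    NumericVector edge_p_release, LogicalVector edge_tm,
                    LogicalVector edge_rebound,
                    double tm_U, double tm_tau_f, double tm_tau_d,
                    double reb_t_delay_steps, double reb_tau,
                    double reb_w,
                    IntegerVector ext_step, IntegerVector ext_target,
                    NumericVector ext_weight,
                    int n_steps, double dt) {
  const int n_edges = edge_pre.size();

  // adjacency: edges grouped by presynaptic neuron
  std::vector<int> deg(n_neurons, 0);
  for (int e = 0; e < n_edges; ++e) deg[edge_pre[e]]++;
  std::vector<int> off(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(n_edges);
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int e = 0; e < n_edges; ++e) adj[cur[edge_pre[e]]++] = e;
  }

  // per-step decay factors
  std::vector<double> dm(n_neurons), gm(n_neurons);
  for (int i = 0; i < n_neurons; ++i) {
    dm[i] = std::exp(-dt / tau_m[i]);
    gm[i] = tau_m[i] / C_m[i] * (1.0 - dm[i]);
  }
  const double de = std::exp(-dt / tau_syn_exc);
  const double di = std::exp(-dt / tau_syn_inh);
  const double ds = reb_tau > 0 ? std::exp(-dt / reb_tau) : 0.0;
  // the membrane update holds the current constant over the step; using the
  // step-mean of the exponentially decaying accumulator (instead of its
  // start-of-step value) removes the O(dt/tau_syn) charge bias, so halving
  // dt leaves rates essentially unchanged
  const double me = tau_syn_exc / dt * (1.0 - de);
  const double mi = tau_syn_inh / dt * (1.0 - di);
  const double ms = reb_tau > 0 ? reb_tau / dt * (1.0 - ds) : 0.0;

  // ring buffer of pending events
  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e) {
    int d = edge_delay_steps[e];
    if (d < 1) stop("synaptic delay shorter than one step (edge %d)", e + 1);
    int total = d + (edge_rebound[e] ? (int)reb_t_delay_steps : 0);
    if (total > max_delay) max_delay = total;
  }
  const int ring = max_delay + 1;
  std::vector<std::vector<Ev>> pending(ring);

  std::vector<double> V(n_neurons), Ie(n_neurons, 0.0), Ii(n_neurons, 0.0),
      Is(n_neurons, 0.0);
  for (int i = 0; i < n_neurons; ++i) V[i] = E_L[i];
  std::vector<int> ref_until(n_neurons, -1);

  // TM state per edge
  std::vector<double> tm_u(n_edges, 0.0), tm_x(n_edges, 1.0),
      tm_t(n_edges, -1e18);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> spiked;
  spiked.reserve(64);

  int ext_i = 0;
  const int n_ext = ext_step.size();
  RNGScope rng;

  for (int k = 0; k < n_steps; ++k) {
    // 1. decay
    for (int i = 0; i < n_neurons; ++i) {
      Ie[i] *= de; Ii[i] *= di; Is[i] *= ds;
    }
    // 2. deliver external events due this step
    while (ext_i < n_ext && ext_step[ext_i] == k) {
      double w = ext_weight[ext_i];
      int tgt = ext_target[ext_i];
      if (w >= 0) Ie[tgt] += w; else Ii[tgt] += w;
      ++ext_i;
    }
    // ... and queued synaptic events
    std::vector<Ev> &due = pending[k % ring];
    for (size_t j = 0; j < due.size(); ++j) {
      const Ev &ev = due[j];
      if (ev.slow) Is[ev.post] += ev.w;
      else if (ev.w >= 0) Ie[ev.post] += ev.w;
      else Ii[ev.post] += ev.w;
    }
    due.clear();
    // 3. membranes
    for (int i = 0; i < n_neurons; ++i) {
      if (k <= ref_until[i]) { V[i] = V_reset[i]; continue; }
      double I = Ie[i] * me + Ii[i] * mi + Is[i] * ms;
      V[i] = E_L[i] + (V[i] - E_L[i]) * dm[i] + I * gm[i];
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential: neuron %d at t=%.1f ms",
             i + 1, (k + 1) * dt);
    }
    // 4. threshold / reset
    spiked.clear();
    const double t_now = (k + 1) * dt;
    for (int i = 0; i < n_neurons; ++i) {
      if (k <= ref_until[i]) continue;
      if (V[i] >= theta[i]) {
        V[i] = V_reset[i];
        ref_until[i] = k + t_ref_steps[i];
        spike_t.push_back(t_now);
        spike_id.push_back(i + 1);
        spiked.push_back(i);
      }
    }
    // 5. propagate
    for (size_t s = 0; s < spiked.size(); ++s) {
      int pre = spiked[s];
      for (int a = off[pre]; a < off[pre + 1]; ++a) {
        int e = adj[a];
        double w = edge_w[e];
        if (edge_tm[e]) {
          double gap = t_now - tm_t[e];
          double u = tm_u[e], x = tm_x[e];
          if (tm_t[e] > -1e17) {
            u *= (tm_tau_f > 0) ? std::exp(-gap / tm_tau_f) : 0.0;
            x = 1.0 - (1.0 - x) * ((tm_tau_d > 0) ? std::exp(-gap / tm_tau_d) : 0.0);
          }
          u += tm_U * (1.0 - u);
          double factor = u * x;
          x *= (1.0 - u);
          tm_u[e] = u; tm_x[e] = x; tm_t[e] = t_now;
          w *= factor / tm_U;
        }
        bool transmit = edge_p_release[e] >= 1.0 ||
                        unif_rand() < edge_p_release[e];
        int arrive = k + edge_delay_steps[e];
        if (transmit && arrive < n_steps) {
          Ev ev; ev.post = edge_post[e]; ev.w = w; ev.slow = false;
          pending[arrive % ring].push_back(ev);
        }
        if (edge_rebound[e]) {
          int onset = arrive + (int)reb_t_delay_steps;
          if (onset < n_steps) {
            Ev ev; ev.post = edge_post[e]; ev.w = reb_w; ev.slow = true;
            pending[onset % ring].push_back(ev);
          }
        }
      }
    }
  }

  return List::create(_["time_ms"] = wrap(spike_t),
                      _["neuron_id"] = wrap(spike_id));
}
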