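#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Inner simulation loop.  Per step (time t_k = t0 + k*dt):
//   1. exponential conductance decay
//   2. I_total = noise + stimulus + conductance-based synaptic current
//   3. forward-Euler Izhikevich membrane update (simultaneous in V, u)
//   4. spike detection (V >= v_thresh) and reset (V <- c, u <- u + d_reset)
//   5. spike delivery through the three projections (PY->PY depressed)
//   6. depression recovery toward 1, then multiplicative depression of spikers
//   7. trace recording
// Noise is drawn from R's RNG: all excitatory draws first, then inhibitory,
// matching runif(n_ex, 0, max) followed by runif(n_in, 0, max) in the pure-R
// reference engine, so the two backends are draw-for-draw identical.
// [[Rcpp::export]]
List sim_core_cpp(List state, List net, List prm,
                  NumericVector stim_ex, NumericVector stim_in,
                  int nsteps, double dt, double t0,
                  IntegerVector trace_ex, IntegerVector trace_in) {
  NumericVector Vex = clone(as<NumericVector>(state["v_ex"]));
  NumericVector Uex = clone(as<NumericVector>(state["u_ex"]));
  NumericVector Vin = clone(as<NumericVector>(state["v_in"]));
  NumericVector Uin = clone(as<NumericVector>(state["u_in"]));
  NumericVector Gex_py = clone(as<NumericVector>(state["g_ex_py"]));
  NumericVector Gin_py = clone(as<NumericVector>(state["g_in_py"]));
  NumericVector Gex_in = clone(as<NumericVector>(state["g_ex_in"]));
  NumericVector Ddep  = clone(as<NumericVector>(state["d_dep"]));

  IntegerVector pp_idx = net["py_py_idx"], pp_ptr = net["py_py_ptr"];
  IntegerVector pi_idx = net["py_in_idx"], pi_ptr = net["py_in_ptr"];
  IntegerVector ip_idx = net["in_py_idx"], ip_ptr = net["in_py_ptr"];
  const double w_pp = as<double>(net["w_py_py"]);
  const double w_pi = as<double>(net["w_py_in"]);
  const double w_ip = as<double>(net["w_in_py"]);

  NumericVector a_ex = prm["a_ex"], b_ex = prm["b_ex"],
                c_ex = prm["c_ex"], d_ex = prm["d_ex"];
  NumericVector a_in = prm["a_in"], b_in = prm["b_in"],
                c_in = prm["c_in"], d_in = prm["d_in"];
  const double tau_ex = as<double>(prm["tau_ex"]);
  const double tau_in = as<double>(prm["tau_in"]);
  const double tau_d  = as<double>(prm["tau_d"]);
  const double r_dep  = as<double>(prm["r_dep"]);
  const double nmax_ex = as<double>(prm["noise_max_ex"]);
  const double nmax_in = as<double>(prm["noise_max_in"]);
  const double nbase_ex = as<double>(prm["noise_base_ex"]);
  const double nbase_in = as<double>(prm["noise_base_in"]);
  const double v_thr  = as<double>(prm["v_thresh"]);
  const double v_ampa = as<double>(prm["v_ampa"]);
  const double v_gaba = as<double>(prm["v_gaba"]);

  const int n_ex = Vex.size(), n_in = Vin.size();
  const double dec_ex = std::exp(-dt / tau_ex);
  const double dec_in = std::exp(-dt / tau_in);
  const double rec_d  = std::exp(-dt / tau_d);

  std::vector<int> sp_step_ex, sp_id_ex, sp_step_in, sp_id_in;
  std::vector<int> spikers_ex, spikers_in;
  spikers_ex.reserve(n_ex);
  spikers_in.reserve(n_in);

  const int ntr_ex = trace_ex.size(), ntr_in = trace_in.size();
  NumericMatrix tr_ex(ntr_ex > 0 ? nsteps : 0, ntr_ex);
  NumericMatrix tr_in(ntr_in > 0 ? nsteps : 0, ntr_in);

  for (int k = 0; k < nsteps; ++k) {
    // 1. decay
    for (int i = 0; i < n_ex; ++i) {
      Gex_py[i] *= dec_ex;
      Gin_py[i] *= dec_in;
    }
    for (int i = 0; i < n_in; ++i) Gex_in[i] *= dec_ex;

    // 2-3. input currents + membrane update (excitatory first: RNG order)
    const double se = stim_ex[k], si = stim_in[k];
    for (int i = 0; i < n_ex; ++i) {
      const double noise = nbase_ex + R::runif(0.0, nmax_ex);
      const double V = Vex[i], u = Uex[i];
      const double I = noise + se
        - Gex_py[i] * (V - v_ampa) - Gin_py[i] * (V - v_gaba);
      const double Vn = V + dt * (0.04 * V * V + 5.0 * V + 140.0 - u + I);
      const double un = u + dt * a_ex[i] * (b_ex[i] * V - u);
      if (!std::isfinite(Vn) || !std::isfinite(un))
        stop("non-finite state at step %d, excitatory neuron %d", k + 1, i + 1);
      Vex[i] = Vn;
      Uex[i] = un;
    }
    for (int i = 0; i < n_in; ++i) {
      const double noise = nbase_in + R::runif(0.0, nmax_in);
      const double V = Vin[i], u = Uin[i];
      const double I = noise + si - Gex_in[i] * (V - v_ampa);
      const double Vn = V + dt * (0.04 * V * V + 5.0 * V + 140.0 - u + I);
      const double un = u + dt * a_in[i] * (b_in[i] * V - u);
      if (!std::isfinite(Vn) || !std::isfinite(un))
        stop("non-finite state at step %d, inhibitory neuron %d", k + 1, i + 1);
      Vin[i] = Vn;
      Uin[i] = un;
    }

    // 4. detect and reset
    spikers_ex.clear();
    for (int i = 0; i < n_ex; ++i) {
      if (Vex[i] >= v_thr) {
        spikers_ex.push_back(i);
        sp_step_ex.push_back(k);
        sp_id_ex.push_back(i + 1);
        Vex[i] = c_ex[i];
        Uex[i] += d_ex[i];
      }
    }
    spikers_in.clear();
    for (int i = 0; i < n_in; ++i) {
      if (Vin[i] >= v_thr) {
        spikers_in.push_back(i);
        sp_step_in.push_back(k);
        sp_id_in.push_back(i + 1);
        Vin[i] = c_in[i];
        Uin[i] += d_in[i];
      }
    }

    // 5. deliver spikes
    for (size_t s = 0; s < spikers_ex.size(); ++s) {
      const int p = spikers_ex[s];
      const double inc = Ddep[p] * w_pp;
      for (int j = pp_ptr[p]; j < pp_ptr[p + 1]; ++j) Gex_py[pp_idx[j]] += inc;
      for (int j = pi_ptr[p]; j < pi_ptr[p + 1]; ++j) Gex_in[pi_idx[j]] += w_pi;
    }
    for (size_t s = 0; s < spikers_in.size(); ++s) {
      const int q = spikers_in[s];
      for (int j = ip_ptr[q]; j < ip_ptr[q + 1]; ++j) Gin_py[ip_idx[j]] += w_ip;
    }

    // 6. depression: recover, then depress spikers
    for (int i = 0; i < n_ex; ++i) Ddep[i] = 1.0 - (1.0 - Ddep[i]) * rec_d;
    for (size_t s = 0; s < spikers_ex.size(); ++s) Ddep[spikers_ex[s]] *= r_dep;

    // 7. traces (post-reset values)
    for (int t = 0; t < ntr_ex; ++t) tr_ex(k, t) = Vex[trace_ex[t]];
    for (int t = 0; t < ntr_in; ++t) tr_in(k, t) = Vin[trace_in[t]];
  }

  List final_state = List::create(
    _["v_ex"] = Vex, _["u_ex"] = Uex, _["v_in"] = Vin, _["u_in"] = Uin,
    _["g_ex_py"] = Gex_py, _["g_in_py"] = Gin_py, _["g_ex_in"] = Gex_in,
    _["d_dep"] = Ddep);

  return List::create(
    _["spike_step_ex"] = wrap(sp_step_ex), _["spike_id_ex"] = wrap(sp_id_ex),
    _["spike_step_in"] = wrap(sp_step_in), _["spike_id_in"] = wrap(sp_id_in),
    _["traces_ex"] = tr_ex, _["traces_in"] = tr_in,
    _["state"] = final_state);
}
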