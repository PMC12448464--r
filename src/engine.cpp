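// Time-stepped aEIF + conductance-synapse engine.
//
// Internal unit system (coherent): mV, ms, uF, mS, uA.
// A membrane equation written with these units needs no conversion factors:
//   c_m [uF] * dV/dt [mV/ms] = I [uA],  g [mS] * V [mV] = I [uA].
// All unit conversion from user-facing values (pA, nS, ...) happens in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Parameter matrix column layout shared with R (see derived_params()):
// 0 c_m, 1 g_l, 2 E_l, 3 V_th, 4 Delta_T, 5 V_reset, 6 tau_w, 7 alpha, 8 b
enum ParCol { C_M = 0, G_L, E_L, V_TH, DELTA_T, V_RESET, TAU_W, ALPHA, B };

static inline double aeif_dv(const double* p, double V, double w, double Isyn,
                             double exp_cap) {
  double arg = (V - p[V_TH]) / p[DELTA_T];
  if (arg > exp_cap) arg = exp_cap;
  double exp_term = p[G_L] * p[DELTA_T] * std::exp(arg);
  return (p[G_L] * (p[E_L] - V) + exp_term + Isyn - w) / p[C_M];
}

static inline double aeif_dw(const double* p, double V, double w) {
  return (p[ALPHA] * (V - p[V_TH]) - w) / p[TAU_W];
}

// Single-neuron current clamp. I_inj: injected current per step (uA),
// defined on [0, n*dt). Returns the voltage sampled after each step and the
// spike times. During the refractory window V is held at V_reset and w keeps
// evolving; injected current does not move V.
// [[Rcpp::export]]
List aeif_clamp_cpp(NumericVector params, NumericVector I_inj, double dt,
                    double refractory, double exp_cap,
                    double V0, double w0) {
  const double* p = params.begin();
  int n = I_inj.size();
  NumericVector V_out(n);
  std::vector<double> spikes;
  double V = V0, w = w0, refrac = 0.0;
  for (int s = 0; s < n; ++s) {
    if (refrac > 0.0) {
      w += aeif_dw(p, V, w) * dt;
      refrac -= dt;
    } else {
      double dV = aeif_dv(p, V, w, I_inj[s], exp_cap) * dt;
      double dw = aeif_dw(p, V, w) * dt;
      V += dV;
      w += dw;
      if (V >= p[V_TH]) {
        spikes.push_back((s + 1) * dt);
        V = p[V_RESET];
        w += p[B];
        refrac = refractory;
      }
    }
    V_out[s] = V;
  }
  return List::create(_["V"] = V_out, _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["w_final"] = w);
}

struct ReceptorState {
  // One double-exponential conductance per postsynaptic neuron.
  std::vector<double> xd, xr;  // decay / rise exponentials
  double fd, fr;               // per-step decay factors
  double inv_umax;             // peak normalization so gbar is the true peak
  double gbar;                 // peak conductance (mS)
  double E_syn;                // reversal (mV)
  bool nmda;                   // apply Mg-block factor
};

static double kernel_umax(double tau_r, double tau_d) {
  double tpk = std::log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r);
  return std::exp(-tpk / tau_d) - std::exp(-tpk / tau_r);
}

// Full network simulation.
//
// pops:        list of parameter matrices (rows = neurons), one per simulated
//              population; population 0 is the external input (no dynamics,
//              its "spikes" come from input_trains).
// projections: list of lists with fields pre_pop, post_pop (0-based pop
//              indices; pre_pop 0 = external), pre, post (0-based neuron
//              index vectors, one entry per edge), gbar (mS), nmda_ratio,
//              E_syn, tau_rise, tau_decay, tau_rise_nmda, tau_decay_nmda,
//              delay_steps (>= 1).
// input_trains: list of numeric spike-time vectors (ms) for the external
//              population.
// noise_sd:    SD (uA) of additive Gaussian noise on the summed synaptic
//              current, drawn per neuron per step through R's RNG.
// record_g_proj: 0-based projection index whose total conductance time
//              course (per postsynaptic neuron) is recorded, or -1.
// [[Rcpp::export]]
List dg_simulate_cpp(List pops, List projections, List input_trains,
                     double duration, double dt, double refractory,
                     double exp_cap, double noise_sd,
                     double mg_eta, double mg_conc, double mg_gamma,
                     int record_g_proj) {
  int n_steps = (int)std::floor(duration / dt + 0.5);
  int n_pops = pops.size();  // includes external pop 0 with NULL params

  // --- populations ---
  std::vector<NumericMatrix> par(n_pops);
  std::vector<int> psize(n_pops);
  psize[0] = input_trains.size();
  for (int k = 1; k < n_pops; ++k) {
    par[k] = as<NumericMatrix>(pops[k]);
    psize[k] = par[k].nrow();
  }
  std::vector<std::vector<double>> V(n_pops), w(n_pops), refrac(n_pops), Isyn(n_pops);
  std::vector<std::vector<double>> parf(n_pops);  // row-major flat copies
  std::vector<std::vector<std::vector<double>>> spikes(n_pops);
  for (int k = 1; k < n_pops; ++k) {
    V[k].resize(psize[k]);
    w[k].assign(psize[k], 0.0);
    refrac[k].assign(psize[k], 0.0);
    Isyn[k].assign(psize[k], 0.0);
    spikes[k].resize(psize[k]);
    parf[k].resize((size_t)psize[k] * 9);
    for (int i = 0; i < psize[k]; ++i) {
      for (int c = 0; c < 9; ++c) parf[k][(size_t)i * 9 + c] = par[k](i, c);
      V[k][i] = par[k](i, E_L);
    }
  }

  // --- projections: CSR adjacency + receptor states ---
  int n_proj = projections.size();
  std::vector<int> pre_pop(n_proj), post_pop(n_proj), delay(n_proj);
  std::vector<std::vector<int>> csr_off(n_proj), csr_tgt(n_proj);
  // receptor states: one (AMPA or GABA) per projection, plus NMDA for excitatory
  std::vector<std::vector<ReceptorState>> rec(n_proj);
  int max_delay = 1;
  for (int j = 0; j < n_proj; ++j) {
    List pj = projections[j];
    pre_pop[j] = as<int>(pj["pre_pop"]);
    post_pop[j] = as<int>(pj["post_pop"]);
    delay[j] = std::max(1, as<int>(pj["delay_steps"]));
    max_delay = std::max(max_delay, delay[j]);
    IntegerVector pre = pj["pre"], post = pj["post"];
    int npre = psize[pre_pop[j]];
    csr_off[j].assign(npre + 1, 0);
    for (int e = 0; e < pre.size(); ++e) csr_off[j][pre[e] + 1]++;
    for (int i = 0; i < npre; ++i) csr_off[j][i + 1] += csr_off[j][i];
    csr_tgt[j].resize(pre.size());
    std::vector<int> cur(csr_off[j].begin(), csr_off[j].end() - 1);
    for (int e = 0; e < pre.size(); ++e) csr_tgt[j][cur[pre[e]]++] = post[e];

    double gbar = as<double>(pj["gbar"]);
    double nmda_ratio = as<double>(pj["nmda_ratio"]);
    double E_syn = as<double>(pj["E_syn"]);
    int npost = psize[post_pop[j]];
    ReceptorState fast;
    double tr = as<double>(pj["tau_rise"]), td = as<double>(pj["tau_decay"]);
    fast.xd.assign(npost, 0.0);
    fast.xr.assign(npost, 0.0);
    fast.fd = std::exp(-dt / td);
    fast.fr = std::exp(-dt / tr);
    fast.inv_umax = 1.0 / kernel_umax(tr, td);
    fast.gbar = gbar;
    fast.E_syn = E_syn;
    fast.nmda = false;
    rec[j].push_back(fast);
    if (nmda_ratio > 0.0 && gbar > 0.0) {
      ReceptorState nm;
      double trn = as<double>(pj["tau_rise_nmda"]), tdn = as<double>(pj["tau_decay_nmda"]);
      nm.xd.assign(npost, 0.0);
      nm.xr.assign(npost, 0.0);
      nm.fd = std::exp(-dt / tdn);
      nm.fr = std::exp(-dt / trn);
      nm.inv_umax = 1.0 / kernel_umax(trn, tdn);
      nm.gbar = gbar * nmda_ratio;
      nm.E_syn = E_syn;
      nm.nmda = true;
      rec[j].push_back(nm);
    }
  }

  // --- external input spikes as per-step index lists ---
  std::vector<std::vector<int>> in_steps(psize[0]);
  for (int i = 0; i < psize[0]; ++i) {
    NumericVector tr = input_trains[i];
    for (double t : tr) {
      int s = (int)std::floor(t / dt);
      if (s >= 0 && s < n_steps) in_steps[i].push_back(s);
    }
    std::sort(in_steps[i].begin(), in_steps[i].end());
  }
  std::vector<size_t> in_ptr(psize[0], 0);

  // --- delayed-delivery ring buffer: (projection, postsynaptic index) ---
  int ring_n = max_delay + 1;
  std::vector<std::vector<std::pair<int, int>>> ring(ring_n);

  NumericMatrix g_rec;
  if (record_g_proj >= 0) g_rec = NumericMatrix(n_steps, psize[post_pop[record_g_proj]]);

  bool use_noise = noise_sd > 0.0;

  // Mg-block factor cache: populations receiving NMDA input get their
  // voltage-dependent unblocked fraction computed once per step.
  std::vector<bool> need_block(n_pops, false);
  for (int j = 0; j < n_proj; ++j)
    if (rec[j].size() > 1) need_block[post_pop[j]] = true;
  std::vector<std::vector<double>> sblock(n_pops);
  for (int k = 1; k < n_pops; ++k)
    if (need_block[k]) sblock[k].assign(psize[k], 1.0);

  for (int s = 0; s < n_steps; ++s) {
    // 1. queue deliveries from external spikes at this step
    for (int i = 0; i < psize[0]; ++i) {
      while (in_ptr[i] < in_steps[i].size() && in_steps[i][in_ptr[i]] == s) {
        for (int j = 0; j < n_proj; ++j) {
          if (pre_pop[j] != 0) continue;
          int slot = (s + delay[j]) % ring_n;
          for (int e = csr_off[j][i]; e < csr_off[j][i + 1]; ++e)
            ring[slot].push_back({j, csr_tgt[j][e]});
        }
        in_ptr[i]++;
      }
    }
    // 2. deliver spikes scheduled for this step
    int slot_now = s % ring_n;
    for (auto& d : ring[slot_now]) {
      for (auto& rc : rec[d.first]) {
        rc.xd[d.second] += 1.0;
        rc.xr[d.second] += 1.0;
      }
    }
    ring[slot_now].clear();

    // 3. advance synaptic states (exact exponential decay) and accumulate
    // currents; depolarizing when E_syn > V
    for (int k = 1; k < n_pops; ++k) {
      std::fill(Isyn[k].begin(), Isyn[k].end(), 0.0);
      if (need_block[k]) {
        const double* Vp = V[k].data();
        double* sb = sblock[k].data();
        for (int i = 0; i < psize[k]; ++i)
          sb[i] = 1.0 / (1.0 + mg_eta * mg_conc * std::exp(-mg_gamma * Vp[i]));
      }
    }
    for (int j = 0; j < n_proj; ++j) {
      int kp = post_pop[j];
      const double* Vp = V[kp].data();
      double* Ip = Isyn[kp].data();
      const double* sb = need_block[kp] ? sblock[kp].data() : nullptr;
      for (auto& rc : rec[j]) {
        int npost = (int)rc.xd.size();
        double* xd = rc.xd.data();
        double* xr = rc.xr.data();
        const double cg = rc.gbar * rc.inv_umax;
        const double fd = rc.fd, fr = rc.fr, Es = rc.E_syn;
        if (rc.nmda) {
          for (int i = 0; i < npost; ++i) {
            xd[i] *= fd;
            xr[i] *= fr;
            double g = cg * (xd[i] - xr[i]) * sb[i];
            Ip[i] += g * (Es - Vp[i]);
          }
        } else {
          for (int i = 0; i < npost; ++i) {
            xd[i] *= fd;
            xr[i] *= fr;
            double g = cg * (xd[i] - xr[i]);
            Ip[i] += g * (Es - Vp[i]);
          }
        }
        if (record_g_proj == j) {
          for (int i = 0; i < npost; ++i) {
            double g = cg * (xd[i] - xr[i]);
            if (rc.nmda) g *= sb[i];
            g_rec(s, i) += g;
          }
        }
      }
    }
    // 4. additive current noise
    if (use_noise) {
      for (int k = 1; k < n_pops; ++k)
        for (int i = 0; i < psize[k]; ++i) Isyn[k][i] += R::rnorm(0.0, noise_sd);
    }
    // 5. step neurons, detect spikes, queue internal deliveries
    for (int k = 1; k < n_pops; ++k) {
      for (int i = 0; i < psize[k]; ++i) {
        const double* pr = &parf[k][(size_t)i * 9];
        if (refrac[k][i] > 0.0) {
          w[k][i] += aeif_dw(pr, V[k][i], w[k][i]) * dt;
          refrac[k][i] -= dt;
          continue;
        }
        double Vi = V[k][i];
        double dV = aeif_dv(pr, Vi, w[k][i], Isyn[k][i], exp_cap) * dt;
        double dw = aeif_dw(pr, Vi, w[k][i]) * dt;
        Vi += dV;
        w[k][i] += dw;
        if (!std::isfinite(Vi) || !std::isfinite(w[k][i]))
          stop("non-finite state in population %d, neuron %d, step %d", k, i + 1, s + 1);
        if (Vi >= pr[V_TH]) {
          double tsp = (s + 1) * dt;
          spikes[k][i].push_back(tsp);
          Vi = pr[V_RESET];
          w[k][i] += pr[B];
          refrac[k][i] = refractory;
          for (int j = 0; j < n_proj; ++j) {
            if (pre_pop[j] != k) continue;
            int slot = (s + delay[j]) % ring_n;
            for (int e = csr_off[j][i]; e < csr_off[j][i + 1]; ++e)
              ring[slot].push_back({j, csr_tgt[j][e]});
          }
        }
        V[k][i] = Vi;
      }
    }
  }

  // flatten spike lists into per-population event vectors
  List out_spikes(n_pops - 1);
  for (int k = 1; k < n_pops; ++k) {
    size_t tot = 0;
    for (auto& v : spikes[k]) tot += v.size();
    IntegerVector id((R_xlen_t)tot);
    NumericVector tm((R_xlen_t)tot);
    size_t q = 0;
    for (int i = 0; i < psize[k]; ++i)
      for (double t : spikes[k][i]) {
        id[q] = i + 1;
        tm[q] = t;
        ++q;
      }
    out_spikes[k - 1] = List::create(_["neuron"] = id, _["time"] = tm);
  }
  List out = List::create(_["spikes"] = out_spikes, _["n_steps"] = n_steps);
  if (record_g_proj >= 0) out["g_trace"] = g_rec;
  return out;
}
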