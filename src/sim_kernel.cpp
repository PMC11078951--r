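#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Forward-Euler integration of the two-area conductance-based LIF network.
//
// Synaptic kinetics are the double-exponential rise/decay pair
//   dx/dt = -x/tau_r + w * delta(t - t_spike - delay)
//   dg/dt = (-g + x)/tau_d
// aggregated per postsynaptic neuron over three recurrent channels
// (0: excitatory intra-areal, 1: excitatory inter-areal, 2: inhibitory
// intra-areal) plus an external channel sharing excitatory kinetics.
// Aggregation is exact because x is linear in the per-synapse increments.
//
// Synapses are supplied in CSR layout keyed by presynaptic neuron; delays are
// integer step counts; delivery uses a ring buffer of future x-increments.
//
// [[Rcpp::export(name = ".sim_kernel")]]
List sim_kernel(IntegerVector syn_ptr,      // length N+1, CSR offsets
                IntegerVector syn_post,     // 0-based postsynaptic ids
                NumericVector syn_w,        // nS
                IntegerVector syn_delay,    // steps (>= 1)
                IntegerVector syn_chan,     // 0/1/2
                NumericVector lam_bg,       // Hz, per neuron
                NumericVector lam_sti,      // Hz extra while stimulus on
                NumericMatrix sti_epochs,   // k x 2, ms
                NumericVector dgk,          // nS per neuron (0 for inhibitory)
                NumericVector gL,           // nS per neuron
                LogicalVector is_exc,
                NumericVector v0,           // mV initial potentials
                double duration_ms,
                double dt,                  // ms
                List pars,                  // scalar biophysical constants
                NumericMatrix lfp_w,        // N x n_sites spatial weights
                IntegerVector record_neurons, // 0-based, current/adapt traces
                int seed) {
  const int N = lam_bg.size();
  const double C       = as<double>(pars["C"]);        // nF
  const double VL      = as<double>(pars["V_L"]);
  const double vT      = as<double>(pars["v_T"]);
  const double vr      = as<double>(pars["v_r"]);
  const double Vk      = as<double>(pars["V_k"]);
  const double Vrev_i  = as<double>(pars["V_rev_i"]);
  const double tau_k   = as<double>(pars["tau_k"]);
  const double tau_r   = as<double>(pars["tau_r"]);
  const double tau_d_e = as<double>(pars["tau_d_e"]);
  const double tau_d_i = as<double>(pars["tau_d_i"]);
  const double tau_ref = as<double>(pars["tau_ref"]);
  const double ext_w   = as<double>(pars["ext_w"]);    // nS

  const int n_steps = (int)std::llround(duration_ms / dt);
  const int steps_per_ms = (int)std::llround(1.0 / dt);
  const int n_ms = n_steps / steps_per_ms;
  double tau_ref_i = tau_ref;
  if (pars.containsElementNamed("tau_ref_i"))
    tau_ref_i = as<double>(pars["tau_ref_i"]);
  const int refrac_steps = (int)std::llround(tau_ref / dt);
  const int refrac_steps_i = (int)std::llround(tau_ref_i / dt);

  // decay multipliers (forward Euler)
  const double ar  = 1.0 - dt / tau_r;
  const double ade = 1.0 - dt / tau_d_e;
  const double adi = 1.0 - dt / tau_d_i;
  const double bde = dt / tau_d_e;
  const double bdi = dt / tau_d_i;
  const double ak  = 1.0 - dt / tau_k;
  // V' [mV/ms] = I [nS*mV = pA] / C [nF -> pF]
  const double dtC = dt / (C * 1000.0);

  // ring buffer for delayed x increments: D slots x 3 channels x N
  int max_delay = 1;
  for (int s = 0; s < syn_delay.size(); ++s)
    if (syn_delay[s] > max_delay) max_delay = syn_delay[s];
  const int D = max_delay + 1;
  std::vector<double> buf((size_t)D * 3 * N, 0.0);

  // pack the synapse table into one contiguous record stream so spike
  // delivery (the hot path) reads a single sequential array
  struct SynRec { int post; float w; short delay; short chan; };
  std::vector<SynRec> syn((size_t)syn_post.size());
  for (R_xlen_t s = 0; s < syn_post.size(); ++s) {
    syn[s].post = syn_post[s];
    syn[s].w = (float)syn_w[s];
    syn[s].delay = (short)syn_delay[s];
    syn[s].chan = (short)syn_chan[s];
  }

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> gk(N, 0.0);
  std::vector<int> refrac(N, 0);
  std::vector<double> x0(N, 0.0), g0(N, 0.0);  // exc intra
  std::vector<double> x1(N, 0.0), g1(N, 0.0);  // exc inter
  std::vector<double> x2(N, 0.0), g2(N, 0.0);  // inh intra
  std::vector<double> x3(N, 0.0), g3(N, 0.0);  // external

  // external drive: per-neuron Poisson(exp(-lambda*dt)) lookups for the
  // stimulus-off and stimulus-on phases
  std::vector<double> Loff(N), Lon(N);
  for (int i = 0; i < N; ++i) {
    Loff[i] = std::exp(-lam_bg[i] * dt * 1e-3);
    Lon[i]  = std::exp(-(lam_bg[i] + lam_sti[i]) * dt * 1e-3);
  }
  bool any_sti = false;
  for (int i = 0; i < N; ++i) if (lam_sti[i] > 0) { any_sti = true; break; }

  Xoshiro rng((uint64_t)seed * 0x9E3779B9ULL + 17ULL);

  const int n_sites = lfp_w.ncol();
  NumericMatrix lfp(n_ms, n_sites);
  const int n_rec = record_neurons.size();
  NumericMatrix rec_Ie_intra(n_rec > 0 ? n_ms : 0, n_rec);
  NumericMatrix rec_Ie_inter(n_rec > 0 ? n_ms : 0, n_rec);
  NumericMatrix rec_Ii_intra(n_rec > 0 ? n_ms : 0, n_rec);
  NumericMatrix rec_gk(n_rec > 0 ? n_ms : 0, n_rec);
  NumericMatrix rec_V(n_rec > 0 ? n_ms : 0, n_rec);

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve((size_t)(N * duration_ms * 0.01));
  spk_t.reserve((size_t)(N * duration_ms * 0.01));

  // stimulus epoch bookkeeping (piecewise-constant rate)
  int n_ep = sti_epochs.nrow();

  for (int step = 0; step < n_steps; ++step) {
    const double t_ms = step * dt;
    const int slot = step % D;
    double *inc0 = &buf[((size_t)slot * 3 + 0) * N];
    double *inc1 = &buf[((size_t)slot * 3 + 1) * N];
    double *inc2 = &buf[((size_t)slot * 3 + 2) * N];

    bool sti_on = false;
    if (any_sti) {
      for (int e = 0; e < n_ep; ++e) {
        if (t_ms >= sti_epochs(e, 0) && t_ms < sti_epochs(e, 1)) {
          sti_on = true;
          break;
        }
      }
    }
    const double *Lcur = sti_on ? Lon.data() : Loff.data();

    // synaptic conductance update (g from pre-update x, then x decay + input)
    for (int i = 0; i < N; ++i) {
      g0[i] = g0[i] * ade + x0[i] * bde;
      x0[i] = x0[i] * ar + inc0[i];
      inc0[i] = 0.0;
    }
    for (int i = 0; i < N; ++i) {
      g1[i] = g1[i] * ade + x1[i] * bde;
      x1[i] = x1[i] * ar + inc1[i];
      inc1[i] = 0.0;
    }
    for (int i = 0; i < N; ++i) {
      g2[i] = g2[i] * adi + x2[i] * bdi;
      x2[i] = x2[i] * ar + inc2[i];
      inc2[i] = 0.0;
    }
    // external channel: Poisson arrivals enter the rise variable immediately
    for (int i = 0; i < N; ++i) {
      g3[i] = g3[i] * ade + x3[i] * bde;
      double xn = x3[i] * ar;
      int k = rng.poisson(Lcur[i]);
      if (k > 0) xn += ext_w * k;
      x3[i] = xn;
    }

    // membrane + adaptation + threshold
    for (int i = 0; i < N; ++i) {
      gk[i] *= ak;
      if (refrac[i] > 0) {
        --refrac[i];
        V[i] = vr;
        continue;
      }
      const double v = V[i];
      const double I = -gL[i] * (v - VL) - gk[i] * (v - Vk) -
                       (g0[i] + g1[i] + g3[i]) * v - g2[i] * (v - Vrev_i);
      double vn = v + dtC * I;
      if (vn >= vT) {
        spk_id.push_back(i);
        spk_t.push_back(t_ms + dt);
        gk[i] += dgk[i];
        refrac[i] = is_exc[i] ? refrac_steps : refrac_steps_i;
        vn = vr;
        // deliver to postsynaptic targets
        for (int s = syn_ptr[i]; s < syn_ptr[i + 1]; ++s) {
          const SynRec &r = syn[s];
          const int dslot = (step + r.delay) % D;
          buf[((size_t)dslot * 3 + r.chan) * N + r.post] += r.w;
        }
      }
      V[i] = vn;
    }

    if (!std::isfinite(V[0]))
      stop("integration diverged at t = %.2f ms", t_ms);

    // 1 kHz sampling of LFP proxy and optional current decomposition
    if ((step + 1) % steps_per_ms == 0) {
      const int ms = step / steps_per_ms;
      if (n_sites > 0) {
        for (int s = 0; s < n_sites; ++s) {
          double acc = 0.0;
          for (int i = 0; i < N; ++i) {
            const double w = lfp_w(i, s);
            if (w == 0.0) continue;
            const double ve = std::fabs(V[i]);
            acc += w * ((g0[i] + g1[i]) * ve + g2[i] * std::fabs(V[i] - Vrev_i));
          }
          lfp(ms, s) = acc;
        }
      }
      for (int r = 0; r < n_rec; ++r) {
        const int i = record_neurons[r];
        rec_Ie_intra(ms, r) = g0[i] * std::fabs(V[i]);
        rec_Ie_inter(ms, r) = g1[i] * std::fabs(V[i]);
        rec_Ii_intra(ms, r) = g2[i] * std::fabs(V[i] - Vrev_i);
        rec_gk(ms, r) = gk[i];
        rec_V(ms, r) = V[i];
      }
    }
  }

  return List::create(
      _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["lfp"] = lfp,
      _["I_e_intra"] = rec_Ie_intra,
      _["I_e_inter"] = rec_Ie_inter,
      _["I_i_intra"] = rec_Ii_intra,
      _["g_k"] = rec_gk,
      _["V"] = rec_V);
}

// Distance-dependent Bernoulli pair sampling for one projection class.
// Probabilities P0 * exp(-d / tauP) are looked up from a table indexed by the
// integer (2*dx)^2 + (2*dy)^2 (coordinates live on half-integer or integer
// lattices, so 2*delta is always integral).
//
// [[Rcpp::export(name = ".sample_pairs")]]
List sample_pairs(NumericVector pre_x, NumericVector pre_y,
                  NumericVector post_x, NumericVector post_y,
                  double P0, double tauP, double L,
                  LogicalVector pre_allowed, bool exclude_self, int seed) {
  const int npre = pre_x.size(), npost = post_x.size();
  if (tauP <= 0) stop("non-positive connection decay constant");
  if (P0 < 0 || P0 > 1) stop("peak connection probability outside [0, 1]");
  const double half = L / 2.0;
  // lookup table over q = (2 dx)^2 + (2 dy)^2, dx, dy in [-L/2, L/2]
  const int qmax = (int)std::llround(2.0 * (L * L)) + 1;
  std::vector<double> ptab(qmax + 1);
  for (int q = 0; q <= qmax; ++q)
    ptab[q] = P0 * std::exp(-std::sqrt((double)q) / (2.0 * tauP));

  Xoshiro rng((uint64_t)seed * 0x51f15ee5ULL + 99ULL);
  std::vector<int> pre_out, post_out;
  pre_out.reserve((size_t)(P0 * npre * npost * 0.02) + 64);
  post_out.reserve(pre_out.capacity());

  for (int j = 0; j < npost; ++j) {
    const double px = post_x[j], py = post_y[j];
    for (int i = 0; i < npre; ++i) {
      if (!pre_allowed[i]) continue;
      double dx = std::fabs(pre_x[i] - px);
      if (dx > half) dx = L - dx;
      double dy = std::fabs(pre_y[i] - py);
      if (dy > half) dy = L - dy;
      if (exclude_self && dx == 0.0 && dy == 0.0 && i == j) continue;
      const int q = (int)std::llround(4.0 * (dx * dx + dy * dy));
      if (rng.unif() < ptab[q]) {
        pre_out.push_back(i + 1);   // 1-based for R
        post_out.push_back(j + 1);
      }
    }
  }
  return List::create(_["pre"] = IntegerVector(pre_out.begin(), pre_out.end()),
                      _["post"] = IntegerVector(post_out.begin(), post_out.end()));
}
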