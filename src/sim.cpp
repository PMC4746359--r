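// Clock-driven simulator for the conductance-based integrate-and-fire
// network.  All randomness comes from internal PCG32 streams so that runs
// are bit-reproducible across platforms and so that the background / P-unit
// / stimulator streams are independent: attaching a stimulator does not
// perturb the background draws, which keeps pre-stimulation activity of a
// lesioned and a lesioned+stimulated run identical.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform on (0, 1)
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

}  // namespace

// [[Rcpp::export]]
List sim_core(List net, double duration, NumericMatrix p_rates,
              SEXP callback, IntegerVector stim_target,
              NumericMatrix stim_rate, NumericVector stim_w, int seed_bg,
              int seed_p, int seed_stim, double dt) {
  const int n = as<int>(net["n_neuron"]);
  const int n_p = as<int>(net["n_p"]);

  NumericVector v_rest = net["v_rest"], v_thresh = net["v_thresh"],
                v_reset = net["v_reset"], tau_m = net["tau_m"],
                th_jump = net["th_jump"], tau_th = net["tau_th"],
                hyp_jump = net["hyp_jump"], tau_hyp = net["tau_hyp"];
  NumericVector e_rev = net["e_rev"], tau_syn = net["tau_syn"];
  const double nmda_vhalf = as<double>(net["nmda_vhalf"]);
  const double nmda_vslope = as<double>(net["nmda_vslope"]);
  const double g_scale = as<double>(net["g_scale"]);
  NumericVector bg_rate = net["bg_rate"];
  const double bg_w = as<double>(net["bg_weight"]);
  LogicalVector silenced = net["silenced"];
  IntegerVector syn_pre = net["syn_pre"], syn_post = net["syn_post"],
                syn_rec = net["syn_rec"], syn_delay = net["syn_delay"];
  NumericVector syn_w = net["syn_w"];

  const int n_syn = syn_pre.size();
  const int n_units = n + n_p;
  const int steps_per_ms = (int)std::lround(1.0 / dt);
  const int n_ms = (int)std::ceil(duration - 1e-9);
  const int n_steps = n_ms * steps_per_ms;
  const int n_stim = stim_target.size();

  // CSR adjacency over presynaptic unit (neurons then P generators)
  std::vector<int> deg(n_units + 1, 0);
  for (int s = 0; s < n_syn; ++s) {
    int p = syn_pre[s];
    if (p < 0 || p >= n_units) stop("synapse with invalid presynaptic id");
    if (syn_post[s] < 0 || syn_post[s] >= n)
      stop("synapse with invalid postsynaptic id");
    deg[p + 1]++;
  }
  for (int i = 0; i < n_units; ++i) deg[i + 1] += deg[i];
  std::vector<int> adj(n_syn);
  {
    std::vector<int> fill(deg.begin(), deg.end() - 1);
    for (int s = 0; s < n_syn; ++s) adj[fill[syn_pre[s]]++] = s;
  }

  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s)
    if (syn_delay[s] > max_delay) max_delay = syn_delay[s];
  const int n_slots = max_delay + 1;

  // ring buffer of future conductance increments: slot x neuron x receptor
  std::vector<double> ring((size_t)n_slots * n * 3, 0.0);
  std::vector<double> g((size_t)n * 3, 0.0);
  std::vector<double> V(n), th(n), hyp(n, 0.0);
  for (int i = 0; i < n; ++i) {
    V[i] = v_rest[i];
    th[i] = v_thresh[i];
  }

  double dec[3];
  for (int r = 0; r < 3; ++r) dec[r] = std::exp(-dt / tau_syn[r]);
  std::vector<double> dec_hyp(n), dec_th(n);
  for (int i = 0; i < n; ++i) {
    dec_hyp[i] = std::exp(-dt / tau_hyp[i]);
    dec_th[i] = std::exp(-dt / tau_th[i]);
  }

  Pcg32 rng_bg((uint64_t)seed_bg * 0x9E3779B97F4A7C15ULL + 11ULL, 54u);
  Pcg32 rng_p((uint64_t)seed_p * 0x9E3779B97F4A7C15ULL + 23ULL, 113u);
  Pcg32 rng_st((uint64_t)seed_stim * 0x9E3779B97F4A7C15ULL + 37ULL, 211u);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<int> stim_sp_id;
  std::vector<double> stim_sp_t;
  sp_id.reserve(4096);
  sp_t.reserve(4096);

  Function cb = R_NilValue == callback ? Function("identity") : Function(callback);
  const bool has_cb = callback != R_NilValue;
  std::vector<double> cur_rates(n_p > 0 ? n_p : 1, 0.0);
  for (int j = 0; j < n_p; ++j) cur_rates[j] = p_rates(j, 0);
  IntegerVector ms_counts(n);  // per-neuron spike count in current ms

  const double p_bg = dt * 1e-3;  // Bernoulli prob = rate(Hz) * dt(ms) / 1000

  auto deliver = [&](int unit, int step) {
    for (int k = deg[unit]; k < deg[unit + 1]; ++k) {
      int s = adj[k];
      int slot = (step + syn_delay[s]) % n_slots;
      ring[((size_t)slot * n + syn_post[s]) * 3 + syn_rec[s]] +=
          syn_w[s] * g_scale;
    }
  };

  for (int step = 0; step < n_steps; ++step) {
    const int ms = step / steps_per_ms;
    const double t_now = (step + 1) * dt;  // spikes stamped end-of-step
    const int slot = step % n_slots;

    // due synaptic increments
    {
      double* rs = &ring[(size_t)slot * n * 3];
      for (int i = 0; i < 3 * n; ++i) {
        g[i] += rs[i];
        rs[i] = 0.0;
      }
    }

    // background Poisson drive (drawn for every neuron, lesioned or not,
    // so the stream does not depend on the silenced set)
    for (int i = 0; i < n; ++i) {
      if (bg_rate[i] > 0 && rng_bg.unif() < bg_rate[i] * p_bg)
        g[(size_t)i * 3 + 0] += bg_w * g_scale;
    }

    // P generators
    for (int j = 0; j < n_p; ++j) {
      double r = has_cb ? cur_rates[j] : p_rates(j, ms);
      if (r > 0 && rng_p.unif() < r * p_bg) {
        sp_id.push_back(n + j);
        sp_t.push_back(t_now);
        deliver(n + j, step);
      }
    }

    // attached stimulators (AMPA onto their target, one-step delay)
    for (int s = 0; s < n_stim; ++s) {
      double r = stim_rate(s, ms);
      if (r > 0 && rng_st.unif() < r * p_bg) {
        stim_sp_id.push_back(s + 1);
        stim_sp_t.push_back(t_now);
        int slot2 = (step + 1) % n_slots;
        ring[((size_t)slot2 * n + stim_target[s]) * 3 + 0] +=
            stim_w[s] * g_scale;
      }
    }

    // membrane update + spike detection
    for (int i = 0; i < n; ++i) {
      double* gi = &g[(size_t)i * 3];
      if (silenced[i]) {
        gi[0] *= dec[0];
        gi[1] *= dec[1];
        gi[2] *= dec[2];
        continue;
      }
      double v = V[i];
      double gate = 1.0 / (1.0 + std::exp(-(v - nmda_vhalf) / nmda_vslope));
      double isyn = gi[0] * (e_rev[0] - v) + gi[1] * gate * (e_rev[1] - v) +
                    gi[2] * (e_rev[2] - v);
      v += dt * ((v_rest[i] - v - hyp[i]) / tau_m[i] + isyn);
      gi[0] *= dec[0];
      gi[1] *= dec[1];
      gi[2] *= dec[2];
      hyp[i] *= dec_hyp[i];
      th[i] = v_thresh[i] + (th[i] - v_thresh[i]) * dec_th[i];
      if (v >= th[i]) {
        sp_id.push_back(i);
        sp_t.push_back(t_now);
        ms_counts[i]++;
        v = v_reset[i];
        th[i] += th_jump[i];
        hyp[i] += hyp_jump[i];
        deliver(i, step);
      }
      if (!std::isfinite(v)) stop("non-finite membrane potential at t=%f", t_now);
      V[i] = v;
    }

    // end of a 1 ms block: hand spike counts to the closed-loop callback,
    // which returns the P rates for the next block
    if ((step + 1) % steps_per_ms == 0) {
      if (has_cb && ms < n_ms - 1) {
        NumericVector nr = cb((double)(ms + 1), ms_counts);
        if ((int)nr.size() != n_p) stop("callback must return one rate per P unit");
        for (int j = 0; j < n_p; ++j) cur_rates[j] = nr[j];
      }
      std::fill(ms_counts.begin(), ms_counts.end(), 0);
    }
  }

  return List::create(
      _["id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["stim_id"] = IntegerVector(stim_sp_id.begin(), stim_sp_id.end()),
      _["stim_time"] = NumericVector(stim_sp_t.begin(), stim_sp_t.end()));
}

// Multi-unit Schoenberg kernel between one spike window and a block of
// stored centers.  `centers` is an L x N x M array (grid points x units x
// centers), `x` is L x N, `tw` the trapezoid quadrature weights (length L).
// Returns the M kernel values sum_n exp(-a * int (lam_c - lam_x)^2 dt).
// [[Rcpp::export]]
NumericVector mu_kernel_block_cpp(NumericVector centers, int L, int N, int M,
                                  NumericMatrix x, double a_lambda,
                                  NumericVector tw) {
  if ((int)centers.size() != L * N * M) stop("centers array size mismatch");
  if (x.nrow() != L || x.ncol() != N) stop("input window dimension mismatch");
  NumericVector out(M);
  const double* C = centers.begin();
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    for (int nidx = 0; nidx < N; ++nidx) {
      const double* cm = C + ((size_t)m * N + nidx) * L;
      const double* xn = &x(0, nidx);
      double acc = 0.0;
      for (int l = 0; l < L; ++l) {
        double d = cm[l] - xn[l];
        acc += tw[l] * d * d;
      }
      s += std::exp(-a_lambda * acc);
    }
    out[m] = s;
  }
  return out;
}
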