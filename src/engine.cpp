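// Clock-driven conductance-based LIF network engine.
//
// Units: time ms, voltage mV, conductance nS, current pA, capacitance pF
// (C = tau_m * g_l).  Synapses are delayed conductance jumps with
// exponential decay; spikes are emitted on threshold crossing, followed by a
// linear voltage ramp from the spike peak down to the reset value over the
// refractory period, after which an exponentially decaying
// after-depolarizing current is injected.
//
// All randomness (background Poisson input) uses R's RNG so runs are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Params {
  double tau_m, g_l, v_rest, v_thr, v_peak, v_reset, tau_ref;
  double adp_amp, tau_adp, tau_e, tau_i, e_exc, e_inh, cap;
};

static Params read_params(const List& np) {
  Params p;
  p.tau_m   = as<double>(np["tau_m"]);
  p.g_l     = as<double>(np["g_l"]);
  p.v_rest  = as<double>(np["v_rest"]);
  p.v_thr   = as<double>(np["v_thr"]);
  p.v_peak  = as<double>(np["v_peak"]);
  p.v_reset = as<double>(np["v_reset"]);
  p.tau_ref = as<double>(np["tau_ref"]);
  p.adp_amp = as<double>(np["adp_amp"]);
  p.tau_adp = as<double>(np["tau_adp"]);
  p.tau_e   = as<double>(np["tau_e"]);
  p.tau_i   = as<double>(np["tau_i"]);
  p.e_exc   = as<double>(np["e_exc"]);
  p.e_inh   = as<double>(np["e_inh"]);
  p.cap     = p.tau_m * p.g_l;
  return p;
}

// CSR adjacency over a source index space of size n_src.
struct Adj {
  std::vector<int> ptr;      // length n_src + 1
  std::vector<int> tgt;
  std::vector<double> w;
  std::vector<int> dstep;
  std::vector<char> inh;
};

static Adj build_adj(int n_src, const IntegerVector& src,
                     const IntegerVector& tgt, const NumericVector& w,
                     const IntegerVector& dstep, const LogicalVector& inh) {
  int m = src.size();
  Adj a;
  a.ptr.assign(n_src + 1, 0);
  for (int i = 0; i < m; ++i) a.ptr[src[i] + 1]++;
  for (int s = 0; s < n_src; ++s) a.ptr[s + 1] += a.ptr[s];
  a.tgt.resize(m); a.w.resize(m); a.dstep.resize(m); a.inh.resize(m);
  std::vector<int> fill(a.ptr.begin(), a.ptr.end() - 1);
  for (int i = 0; i < m; ++i) {
    int at = fill[src[i]]++;
    a.tgt[at] = tgt[i];
    a.w[at] = w[i];
    a.dstep[at] = dstep[i];
    a.inh[at] = inh[i];
  }
  return a;
}

// [[Rcpp::export]]
List engine_run(List np, int n_neurons,
                IntegerVector rec_src, IntegerVector rec_tgt,
                NumericVector rec_w, IntegerVector rec_dstep,
                LogicalVector rec_inh,
                int n_ext,
                IntegerVector ext_src, IntegerVector ext_tgt,
                NumericVector ext_w, IntegerVector ext_dstep,
                LogicalVector ext_inh,
                IntegerVector ext_spike_src, IntegerVector ext_spike_step,
                double bg_rate, double bg_weight,
                double duration, double dt,
                Nullable<List> init_state,
                IntegerVector forced_id, IntegerVector forced_step,
                IntegerVector record_ids,
                NumericVector const_ge, NumericVector const_gi,
                NumericVector i_inject) {
  if (dt <= 0) stop("dt must be > 0");
  Params p = read_params(np);
  const int n_steps = (int) std::floor(duration / dt + 0.5);
  const int n = n_neurons;

  // ring buffer size: one slot per delay step up to the maximum delay
  int max_d = 0;
  for (int i = 0; i < rec_dstep.size(); ++i)
    if (rec_dstep[i] > max_d) max_d = rec_dstep[i];
  for (int i = 0; i < ext_dstep.size(); ++i)
    if (ext_dstep[i] > max_d) max_d = ext_dstep[i];
  const int n_slots = max_d + 1;

  Adj rec = build_adj(n, rec_src, rec_tgt, rec_w, rec_dstep, rec_inh);
  Adj ext = build_adj(n_ext, ext_src, ext_tgt, ext_w, ext_dstep, ext_inh);

  std::vector<double> v(n, p.v_rest), ge(n, 0.0), gi(n, 0.0),
      adp(n, 0.0), refrac(n, 0.0);
  std::vector<double> ring_e((size_t) n_slots * n, 0.0),
      ring_i((size_t) n_slots * n, 0.0);

  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector sv = st["v"], sge = st["ge"], sgi = st["gi"],
        sadp = st["adp"], sref = st["refrac"];
    for (int i = 0; i < n; ++i) {
      v[i] = sv[i]; ge[i] = sge[i]; gi[i] = sgi[i];
      adp[i] = sadp[i]; refrac[i] = sref[i];
    }
    NumericMatrix re = st["ring_exc"], ri = st["ring_inh"];
    int rows = std::min((int) re.nrow(), n_slots);
    for (int s = 0; s < rows; ++s)
      for (int i = 0; i < n; ++i) {
        ring_e[(size_t) s * n + i] = re(s, i);
        ring_i[(size_t) s * n + i] = ri(s, i);
      }
  }

  const double dec_e = std::exp(-dt / p.tau_e);
  const double dec_i = std::exp(-dt / p.tau_i);
  const double dec_adp = std::exp(-dt / p.tau_adp);
  const double bg_lambda = n * bg_rate * dt / 1000.0;

  const int n_rec_v = record_ids.size();
  NumericMatrix vmat(n_rec_v > 0 ? n_steps : 0, n_rec_v);

  std::vector<double> gbar(n, 0.0);
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1024); sp_t.reserve(1024);

  int ext_ptr = 0, forced_ptr = 0;
  const int n_ext_ev = ext_spike_src.size();
  const int n_forced = forced_id.size();
  int slot0 = 0;

  RNGScope scope;

  // enqueue helper over both adjacency sets
  auto enqueue = [&](const Adj& a, int src_idx, int step) {
    for (int k = a.ptr[src_idx]; k < a.ptr[src_idx + 1]; ++k) {
      int slot = slot0 + a.dstep[k];
      if (slot >= n_slots) slot -= n_slots;
      size_t at = (size_t) slot * n + a.tgt[k];
      if (a.inh[k]) ring_i[at] += a.w[k]; else ring_e[at] += a.w[k];
    }
  };

  for (int s = 0; s < n_steps; ++s) {
    // external source spikes emitted at this step
    while (ext_ptr < n_ext_ev && ext_spike_step[ext_ptr] == s) {
      enqueue(ext, ext_spike_src[ext_ptr], s);
      ++ext_ptr;
    }
    if (ext_ptr < n_ext_ev && ext_spike_step[ext_ptr] < s)
      stop("external spike events must be sorted by step");

    // conductance decay, then delivery of this step's arrivals
    double* slot_e = &ring_e[(size_t) slot0 * n];
    double* slot_i = &ring_i[(size_t) slot0 * n];
    for (int i = 0; i < n; ++i) {
      ge[i] = ge[i] * dec_e + slot_e[i];
      gi[i] = gi[i] * dec_i + slot_i[i];
      slot_e[i] = 0.0; slot_i[i] = 0.0;
    }

    // background Poisson drive (independent across neurons)
    if (bg_lambda > 0) {
      int k = (int) R::rpois(bg_lambda);
      for (int j = 0; j < k; ++j) {
        int i = (int) (unif_rand() * n);
        if (i >= n) i = n - 1;
        ge[i] += bg_weight;
      }
    }

    // membrane update
    for (int i = 0; i < n; ++i) {
      double get = ge[i] + const_ge[i];
      double git = gi[i] + const_gi[i];
      gbar[i] += get + git;
      if (refrac[i] > 0) {
        refrac[i] -= dt;
        if (refrac[i] > 1e-12) {
          v[i] = p.v_reset + (p.v_peak - p.v_reset) * refrac[i] / p.tau_ref;
        } else {
          refrac[i] = 0.0;
          v[i] = p.v_reset;
          adp[i] += p.adp_amp;
        }
      } else {
        double dv = (p.g_l * (p.v_rest - v[i]) + get * (p.e_exc - v[i]) +
                     git * (p.e_inh - v[i]) + adp[i] + i_inject[i]) / p.cap;
        v[i] += dt * dv;
        if (!std::isfinite(v[i]))
          stop("non-finite membrane potential at t = %f ms (neuron %d): "
               "integration blow-up", s * dt, i + 1);
      }
      adp[i] *= dec_adp;
    }

    // forced spikes (protocol current-injection commands)
    while (forced_ptr < n_forced && forced_step[forced_ptr] == s) {
      int i = forced_id[forced_ptr];
      if (refrac[i] <= 0) v[i] = p.v_thr + 1.0;
      ++forced_ptr;
    }

    // threshold crossings
    for (int i = 0; i < n; ++i) {
      if (refrac[i] <= 0 && v[i] >= p.v_thr) {
        sp_id.push_back(i + 1);
        sp_t.push_back((s + 1) * dt);
        v[i] = p.v_peak;
        refrac[i] = p.tau_ref;
        enqueue(rec, i, s);
      }
    }

    for (int r = 0; r < n_rec_v; ++r) vmat(s, r) = v[record_ids[r]];

    slot0 = (slot0 + 1) % n_slots;
  }

  // rotate rings so row 0 is the next step's slot
  NumericMatrix out_re(n_slots, n), out_ri(n_slots, n);
  for (int s = 0; s < n_slots; ++s) {
    int from = (slot0 + s) % n_slots;
    for (int i = 0; i < n; ++i) {
      out_re(s, i) = ring_e[(size_t) from * n + i];
      out_ri(s, i) = ring_i[(size_t) from * n + i];
    }
  }
  for (int i = 0; i < n; ++i) gbar[i] /= n_steps;

  return List::create(
      _["spike_id"] = wrap(sp_id),
      _["spike_time"] = wrap(sp_t),
      _["v"] = vmat,
      _["gbar"] = wrap(gbar),
      _["state"] = List::create(
          _["v"] = wrap(v), _["ge"] = wrap(ge), _["gi"] = wrap(gi),
          _["adp"] = wrap(adp), _["refrac"] = wrap(refrac),
          _["ring_exc"] = out_re, _["ring_inh"] = out_ri));
}

// Backward-in-time lookup table kappa for the fast eligibility path.
//
// kappa[k, j] = sum_{s >= k} dt * exp(-(n-1-s)*dt/tau_p) * H[s, j] *
//               eps((s-k)*dt; tau_slow[j], tau_fast[j])
// with eps a peak-normalized difference of exponentials (alpha function in
// the equal-constant limit).  Two first-order backward recursions per
// column; O(n_steps) per neuron.
// [[Rcpp::export]]
NumericMatrix kappa_backward(NumericMatrix H, NumericVector tau_slow,
                             NumericVector tau_fast, double tau_p,
                             double dt) {
  const int n = H.nrow(), m = H.ncol();
  NumericMatrix kap(n, m);
  for (int j = 0; j < m; ++j) {
    double ts = tau_slow[j], tf = tau_fast[j];
    double wp_step = std::exp(-dt / tau_p);
    if (std::abs(ts - tf) > 1e-9 * ts) {
      // peak of (e^{-u/ts} - e^{-u/tf}) at u* = log(ts/tf)/(1/tf - 1/ts)
      double ustar = std::log(ts / tf) / (1.0 / tf - 1.0 / ts);
      double peak = std::exp(-ustar / ts) - std::exp(-ustar / tf);
      double ds = std::exp(-dt / ts), df = std::exp(-dt / tf);
      double a = 0.0, b = 0.0, wp = 1.0;  // wp = exp(-(n-1-s)dt/tau_p)
      for (int s = n - 1; s >= 0; --s) {
        double src = dt * wp * H(s, j);
        a = (s == n - 1) ? src : ds * a + src;
        b = (s == n - 1) ? src : df * b + src;
        kap(s, j) = (a - b) / peak;
        wp *= wp_step;
      }
    } else {
      // alpha-function limit: eps(u) = (u/tau) * exp(1 - u/tau)
      double tau = ts, d = std::exp(-dt / tau);
      double u = 0.0, w = 0.0, wp = 1.0;
      for (int s = n - 1; s >= 0; --s) {
        double src = dt * wp * H(s, j);
        if (s == n - 1) { u = src; w = 0.0; }
        else { w = d * (w + dt * u); u = d * u + src; }
        kap(s, j) = w * std::exp(1.0) / tau;
        wp *= wp_step;
      }
    }
  }
  return kap;
}
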