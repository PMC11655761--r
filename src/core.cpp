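#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Synchronous-update engine for a chain of rate-model areas.
//
// Cell indexing: area a (0-based) occupies the flat range [a*n, (a+1)*n) where
// n = cells per area. Every projection is stored as parallel index vectors
// (pre, post, w) over existing synapses only, sorted by (pre, post); masks are
// immutable here by construction (only w is ever written).
//
// Per step, with O_prev the previous excitatory outputs:
//   net_i = ext_i + sum_k w_k O_prev[pre_k] - kL*Oi_prev_i - kG*G_prev[a]
//           - kA*adapt_i + noise
//   V_i  += (net_i - V_i)/tau_m,  O_i = clamp(V_i - phi, 0, 1)
// Inhibitory cells low-pass the g_ei-scaled local sum of excitatory output
// through the same squash; adaptation low-passes own output; G low-passes the
// area-summed output. When learning is on, the ABS-style rule updates every
// synapse from (O_prev[pre], Vp[post]) where Vp is a short low-pass of the
// membrane potential: potentiation and depression require *sustained*
// depolarisation, so brief ignition transients and burst/suppression cycles
// do not drive learning.
//
// For speed the synapse list of each projection is indexed both by source
// (CSR: drives the forward pass and the LTP/homosynaptic-LTD branches, which
// require an active presynaptic cell) and by target (CSC: drives the
// heterosynaptic-LTD branch, which requires a strongly depolarised
// postsynaptic cell). Both passes only visit cells above threshold, so the
// cost per step scales with the number of active cells, not with the number
// of synapses.

static inline double squash(double x) {
  if (x <= 0.0) return 0.0;
  if (x >= 1.0) return 1.0;
  return x;
}

struct Proj {
  int src, tgt;
  // CSR by presynaptic cell
  std::vector<int> ptr;       // size n+1
  std::vector<int> post;      // target cell per synapse (CSR order = input order)
  std::vector<double> w;      // weights, CSR order
  // CSC by postsynaptic cell, holding indices into w
  std::vector<int> cptr;      // size n+1
  std::vector<int> cpre;      // source cell per synapse, CSC order
  std::vector<int> cidx;      // index into w, CSC order
};

struct InhibWiring {
  std::vector<int> ptr;   // CSR by presynaptic (excitatory) cell
  std::vector<int> post;  // inhibitory cell pooled into
};

// [[Rcpp::export]]
List run_core_cpp(List state, List proj, List inhib, List params,
                  NumericMatrix stim, List phases, int record_every) {
  RNGScope rngScope;

  NumericVector V      = clone(as<NumericVector>(state["V"]));
  NumericVector O      = clone(as<NumericVector>(state["O"]));
  NumericVector Vi     = clone(as<NumericVector>(state["Vi"]));
  NumericVector Oi     = clone(as<NumericVector>(state["Oi"]));
  NumericVector adapt  = clone(as<NumericVector>(state["adapt"]));
  NumericVector Vp     = clone(as<NumericVector>(state["Vp"]));
  NumericVector G      = clone(as<NumericVector>(state["G"]));

  const int n_areas = G.size();
  const int N = V.size();
  const int n = N / n_areas;

  const double tau_m  = as<double>(params["tau_membrane"]);
  const double tau_i  = as<double>(params["tau_inhib"]);
  const double tau_a  = as<double>(params["tau_adapt"]);
  const double tau_g  = as<double>(params["tau_global"]);
  const double tau_p  = as<double>(params["tau_plastic"]);
  const double kA     = as<double>(params["adapt_strength"]);
  const double kL     = as<double>(params["local_inhib_gain"]);
  const double kG     = as<double>(params["global_inhib_gain"]);
  const double g_ei   = as<double>(params["inhib_input_gain"]);
  const double noise  = as<double>(params["noise_amplitude"]);
  const double phi    = as<double>(params["output_threshold"]);
  const double w_max  = as<double>(params["w_max"]);
  const double th_pre   = as<double>(params["theta_pre"]);
  const double th_plus  = as<double>(params["theta_plus"]);
  const double th_minus = as<double>(params["theta_minus"]);
  const double dw       = as<double>(params["delta_w"]);
  const double dw_ltd   = as<double>(params["delta_w_ltd"]);
  const double dw_het   = as<double>(params["delta_w_hetero"]);
  const bool hetero_ltd = as<bool>(params["hetero_ltd"]);

  // ---- build per-projection CSR + CSC indices ----
  const int n_proj = proj.size();
  std::vector<Proj> P(n_proj);
  for (int p = 0; p < n_proj; ++p) {
    List pr = proj[p];
    IntegerVector pre  = as<IntegerVector>(pr["pre"]);
    IntegerVector post = as<IntegerVector>(pr["post"]);
    NumericVector w    = as<NumericVector>(pr["w"]);
    const int nnz = pre.size();
    Proj& q = P[p];
    q.src = as<int>(pr["src"]);
    q.tgt = as<int>(pr["tgt"]);
    q.ptr.assign(n + 1, 0);
    q.post.resize(nnz);
    q.w.resize(nnz);
    for (int k = 0; k < nnz; ++k) q.ptr[pre[k] + 1]++;
    for (int i = 0; i < n; ++i) q.ptr[i + 1] += q.ptr[i];
    {
      std::vector<int> cur(q.ptr.begin(), q.ptr.end() - 1);
      for (int k = 0; k < nnz; ++k) {   // input is sorted by pre already
        int at = cur[pre[k]]++;
        q.post[at] = post[k];
        q.w[at] = w[k];
      }
    }
    q.cptr.assign(n + 1, 0);
    q.cpre.resize(nnz);
    q.cidx.resize(nnz);
    for (int k = 0; k < nnz; ++k) q.cptr[q.post[k] + 1]++;
    for (int i = 0; i < n; ++i) q.cptr[i + 1] += q.cptr[i];
    {
      std::vector<int> cur(q.cptr.begin(), q.cptr.end() - 1);
      for (int s = 0; s < n; ++s) {
        for (int k = q.ptr[s]; k < q.ptr[s + 1]; ++k) {
          int at = cur[q.post[k]]++;
          q.cpre[at] = s;
          q.cidx[at] = k;
        }
      }
    }
  }

  // ---- inhibitory pooling wiring (identical per area) ----
  InhibWiring IW;
  {
    List ia = inhib[0];
    IntegerVector pre  = as<IntegerVector>(ia["pre"]);
    IntegerVector post = as<IntegerVector>(ia["post"]);
    const int nnz = pre.size();
    IW.ptr.assign(n + 1, 0);
    IW.post.resize(nnz);
    for (int k = 0; k < nnz; ++k) IW.ptr[pre[k] + 1]++;
    for (int i = 0; i < n; ++i) IW.ptr[i + 1] += IW.ptr[i];
    std::vector<int> cur(IW.ptr.begin(), IW.ptr.end() - 1);
    for (int k = 0; k < nnz; ++k) IW.post[cur[pre[k]]++] = post[k];
  }

  IntegerVector ph_stim     = as<IntegerVector>(phases["stim_id"]);
  IntegerVector ph_dur      = as<IntegerVector>(phases["duration"]);
  LogicalVector ph_learning = as<LogicalVector>(phases["learning"]);
  LogicalVector ph_reset    = as<LogicalVector>(phases["reset"]);
  const int n_phases = ph_dur.size();

  long total_steps = 0;
  for (int p = 0; p < n_phases; ++p) total_steps += ph_dur[p];
  int n_rec = 0;
  if (record_every > 0)
    n_rec = (int)((total_steps + record_every - 1) / record_every);

  NumericMatrix rec_out(n_rec, record_every > 0 ? N : 0);
  IntegerVector rec_step(n_rec);
  NumericMatrix totals(total_steps, n_areas);
  IntegerVector phase_start(n_phases);

  std::vector<double> O_prev(N), Oi_prev(N), acc(N), s_inh(N), G_prev(n_areas);
  std::vector<int> active;       // cells with O_prev >= th_pre (for learning)
  std::vector<int> firing;       // cells with O_prev > 0 (for propagation)
  active.reserve(N); firing.reserve(N);

  long step = 0;
  int rec_i = 0;

  for (int ph = 0; ph < n_phases; ++ph) {
    phase_start[ph] = (int)step + 1;  // 1-based step index of phase onset
    if (ph_reset[ph]) {
      std::fill(V.begin(), V.end(), 0.0);
      std::fill(O.begin(), O.end(), 0.0);
      std::fill(Vi.begin(), Vi.end(), 0.0);
      std::fill(Oi.begin(), Oi.end(), 0.0);
      std::fill(adapt.begin(), adapt.end(), 0.0);
      std::fill(Vp.begin(), Vp.end(), 0.0);
      std::fill(G.begin(), G.end(), 0.0);
    }
    const int sid = ph_stim[ph];  // 0 = no input, else 1-based stim column
    const bool learn = ph_learning[ph];

    for (int d = 0; d < ph_dur[ph]; ++d, ++step) {
      std::copy(O.begin(), O.end(), O_prev.begin());
      std::copy(Oi.begin(), Oi.end(), Oi_prev.begin());
      std::copy(G.begin(), G.end(), G_prev.begin());
      firing.clear();
      for (int i = 0; i < N; ++i) if (O_prev[i] > 0.0) firing.push_back(i);

      // accumulate synaptic + external input
      if (sid > 0) {
        for (int i = 0; i < N; ++i) acc[i] = stim(i, sid - 1);
      } else {
        std::fill(acc.begin(), acc.end(), 0.0);
      }
      for (int p = 0; p < n_proj; ++p) {
        const Proj& q = P[p];
        const int sb = q.src * n, tb = q.tgt * n;
        for (size_t f = 0; f < firing.size(); ++f) {
          const int cell = firing[f];
          if (cell < sb || cell >= sb + n) continue;
          const int s = cell - sb;
          const double o = O_prev[cell];
          for (int k = q.ptr[s]; k < q.ptr[s + 1]; ++k)
            acc[tb + q.post[k]] += q.w[k] * o;
        }
      }

      // excitatory membrane + output
      for (int a = 0; a < n_areas; ++a) {
        const int b = a * n;
        const double gterm = kG * G_prev[a];
        for (int i = b; i < b + n; ++i) {
          double net = acc[i] - kL * Oi_prev[i] - gterm - kA * adapt[i];
          if (noise > 0.0) net += noise * (2.0 * unif_rand() - 1.0);
          V[i] += (net - V[i]) / tau_m;
          O[i] = squash(V[i] - phi);
        }
      }

      // inhibitory cells: pooled previous excitatory output
      std::fill(s_inh.begin(), s_inh.end(), 0.0);
      for (size_t f = 0; f < firing.size(); ++f) {
        const int cell = firing[f];
        const int a = cell / n, s = cell - a * n;
        const double o = O_prev[cell];
        for (int k = IW.ptr[s]; k < IW.ptr[s + 1]; ++k)
          s_inh[a * n + IW.post[k]] += o;
      }
      for (int i = 0; i < N; ++i) {
        Vi[i] += (g_ei * s_inh[i] - Vi[i]) / tau_i;
        Oi[i] = squash(Vi[i] - phi);
      }

      // adaptation, plasticity potential trace, slow activity estimate
      for (int i = 0; i < N; ++i) adapt[i] += (O[i] - adapt[i]) / tau_a;
      for (int i = 0; i < N; ++i) Vp[i] += (V[i] - Vp[i]) / tau_p;
      for (int a = 0; a < n_areas; ++a) {
        const int b = a * n;
        double s = 0.0;
        for (int i = b; i < b + n; ++i) s += O[i];
        totals(step, a) = s;
        G[a] += (s - G[a]) / tau_g;
      }

      // ABS-style plasticity
      if (learn && dw > 0.0) {
        active.clear();
        for (int i = 0; i < N; ++i) if (O_prev[i] >= th_pre) active.push_back(i);
        for (int p = 0; p < n_proj; ++p) {
          Proj& q = P[p];
          const int sb = q.src * n, tb = q.tgt * n;
          // active presynaptic cells: LTP / homosynaptic LTD
          for (size_t f = 0; f < active.size(); ++f) {
            const int cell = active[f];
            if (cell < sb || cell >= sb + n) continue;
            const int s = cell - sb;
            for (int k = q.ptr[s]; k < q.ptr[s + 1]; ++k) {
              const double pv = Vp[tb + q.post[k]];
              double wk = q.w[k];
              if (pv >= th_plus) {
                wk += dw;
                if (wk > w_max) wk = w_max;
              } else if (pv >= th_minus) {
                wk -= dw_ltd;
                if (wk < 0.0) wk = 0.0;
              }
              q.w[k] = wk;
            }
          }
          // strongly depolarised postsynaptic cells with silent presynaptic
          // cells: heterosynaptic LTD
          if (hetero_ltd) {
            for (int t = 0; t < n; ++t) {
              if (Vp[tb + t] < th_plus) continue;
              for (int k = q.cptr[t]; k < q.cptr[t + 1]; ++k) {
                if (O_prev[sb + q.cpre[k]] >= th_pre) continue;
                double wk = q.w[q.cidx[k]] - dw_het;
                q.w[q.cidx[k]] = wk < 0.0 ? 0.0 : wk;
              }
            }
          }
        }
      }

      // record
      if (record_every > 0 && (step % record_every) == 0) {
        for (int i = 0; i < N; ++i) rec_out(rec_i, i) = O[i];
        rec_step[rec_i] = (int)step + 1;
        ++rec_i;
      }

      // divergence guard (squash bounds O, but V can carry bad inputs)
      if ((step % 256) == 0) {
        for (int a = 0; a < n_areas; ++a) {
          const int b = a * n;
          for (int i = b; i < b + n; ++i) {
            if (!R_finite(V[i]))
              stop("dynamics diverged: non-finite potential in area %d at step %ld",
                   a + 1, step + 1);
          }
        }
      }
    }
  }
  for (int a = 0; a < n_areas; ++a) {
    const int b = a * n;
    for (int i = b; i < b + n; ++i)
      if (!R_finite(V[i]))
        stop("dynamics diverged: non-finite potential in area %d at step %ld",
             a + 1, total_steps);
  }

  // return weights in the original (pre, post) input order = CSR order
  List w_out(n_proj);
  for (int p = 0; p < n_proj; ++p) w_out[p] = NumericVector(P[p].w.begin(),
                                                            P[p].w.end());

  return List::create(
    _["state"] = List::create(_["V"] = V, _["O"] = O, _["Vi"] = Vi,
                              _["Oi"] = Oi, _["adapt"] = adapt,
                              _["Vp"] = Vp, _["G"] = G),
    _["weights"] = w_out,
    _["outputs"] = rec_out,
    _["rec_step"] = rec_step,
    _["totals"] = totals,
    _["phase_start"] = phase_start);
}
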