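#include <Rcpp.h>
#include "nygren.h"
using namespace Rcpp;
using namespace nyg;

// Anisotropic monodomain solver on a structured grid.
//
// Strang operator splitting at fixed dt: half reaction step (Rush-Larsen /
// Euler cell update, dt/2), full explicit diffusion step, half reaction step.
// The diffusion operator arrives pre-assembled as a sparse CSC matrix A
// (entries approximate div(sigma grad .) with sigma in S/m and dx in um);
// diff_scale = 1e9 / (Sv * cm_area) converts A %*% Vm to mV/ms.
//
// states0:  N_STATE x N matrix of initial states (one column per node)
// variant:  1-based variant index per node into par_mat columns
// par_mat:  7 x n_variant matrix of cell parameters
// stimulus: events (start, dur, amp pA) with flat node index vector + offsets
//
// Returns Vm sampled every sample_dt, per-node activation times (time of max
// dV/dt within each suprathreshold excursion), final states and diagnostics.
// [[Rcpp::export]]
List cpp_run_monodomain(NumericMatrix states0, IntegerVector variant,
                        NumericMatrix par_mat, S4 A, double diff_scale,
                        double dt, double t_end, double sample_dt,
                        NumericVector stim_start, NumericVector stim_dur,
                        NumericVector stim_amp, IntegerVector stim_nodes,
                        IntegerVector stim_offset, bool record_vm,
                        double act_threshold) {
  const int N = states0.ncol();
  if (states0.nrow() != N_STATE) stop("states0 must have %d rows", N_STATE);
  if (variant.size() != N) stop("variant length mismatch");

  const int n_var = par_mat.ncol();
  std::vector<NygPar> pars(n_var);
  std::vector<RateTables> tabs(n_var);
  for (int v = 0; v < n_var; ++v) {
    pars[v] = parFromVector(&par_mat(0, v));
    tabs[v].build(pars[v], dt / 2.0);
  }

  // sparse CSC slots
  IntegerVector Ap = A.slot("p"), Ai = A.slot("i");
  NumericVector Ax = A.slot("x");
  IntegerVector Adim = A.slot("Dim");
  if (Adim[0] != N || Adim[1] != N) stop("diffusion operator dimension mismatch");

  std::vector<double> S((size_t)N_STATE * N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N_STATE; ++i)
      S[(size_t)j * N_STATE + i] = states0(i, j);

  long n_steps = (long)std::llround(t_end / dt);
  long samp_every = (long)std::llround(sample_dt / dt);
  if (samp_every < 1) samp_every = 1;
  long n_samp = n_steps / samp_every + 1;

  NumericMatrix vm_out = record_vm ? NumericMatrix(n_samp, N) : NumericMatrix(0, 0);
  NumericVector t_out(n_samp);

  // activation bookkeeping
  std::vector<std::vector<double> > act(N);
  std::vector<char> excited(N, 0);
  std::vector<double> best_dvdt(N, 0.0), best_t(N, 0.0);

  std::vector<double> lap(N), vm(N);
  std::vector<SlowCache> slow(N);
  long n_upd = (long)std::llround(0.25 / dt);
  if (n_upd < 1) n_upd = 1;
  const int n_ev = stim_start.size();

  if (record_vm) {
    t_out[0] = 0.0;
    for (int j = 0; j < N; ++j) vm_out(0, j) = S[(size_t)j * N_STATE + S_V];
  }
  long is = 1;

  bool diverged = false;
  double t_div = NA_REAL;
  int node_div = NA_INTEGER;

  std::vector<double> istim(N, 0.0);
  for (long k = 0; k < n_steps && !diverged; ++k) {
    double t = k * dt;

    // stimulus currents active during [t, t+dt)
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int e = 0; e < n_ev; ++e) {
      if (t >= stim_start[e] && t < stim_start[e] + stim_dur[e]) {
        for (int q = stim_offset[e]; q < stim_offset[e + 1]; ++q)
          istim[stim_nodes[q]] += stim_amp[e];
      }
    }

    // half reaction
    bool upd = (k % n_upd == 0);
    for (int j = 0; j < N; ++j) {
      double* s = &S[(size_t)j * N_STATE];
      int v = variant[j] - 1;
      if (upd) refreshSlow(s, slow[j]);
      double dv = cellStep(s, pars[v], tabs[v], slow[j], istim[j], dt / 2.0);
      // activation tracking on the reaction sub-step
      double V = s[S_V];
      if (!std::isfinite(V) || std::fabs(V) > 1000.0) {
        diverged = true; t_div = t; node_div = j + 1;
        break;
      }
      if (!excited[j]) {
        if (V > act_threshold) {
          excited[j] = 1;
          best_dvdt[j] = dv; best_t[j] = t;
        }
      } else {
        if (dv > best_dvdt[j] && V < 0.0) { best_dvdt[j] = dv; best_t[j] = t; }
        if (V < act_threshold - 5.0) {
          act[j].push_back(best_t[j]);
          excited[j] = 0;
        }
      }
    }

    // full diffusion step: Vm += dt * diff_scale * (A %*% Vm)
    for (int j = 0; j < N; ++j) vm[j] = S[(size_t)j * N_STATE + S_V];
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int col = 0; col < N; ++col) {
      double xc = vm[col];
      if (xc == 0.0) continue;
      for (int q = Ap[col]; q < Ap[col + 1]; ++q) lap[Ai[q]] += Ax[q] * xc;
    }
    double fac = dt * diff_scale;
    for (int j = 0; j < N; ++j)
      S[(size_t)j * N_STATE + S_V] = vm[j] + fac * lap[j];

    // half reaction
    for (int j = 0; j < N; ++j) {
      double* s = &S[(size_t)j * N_STATE];
      int v = variant[j] - 1;
      cellStep(s, pars[v], tabs[v], slow[j], istim[j], dt / 2.0);
      if (!std::isfinite(s[S_V]) || std::fabs(s[S_V]) > 1000.0) {
        diverged = true; t_div = t; node_div = j + 1;
        break;
      }
    }

    if (!diverged && (k + 1) % samp_every == 0 && is < n_samp) {
      t_out[is] = (k + 1) * dt;
      if (record_vm)
        for (int j = 0; j < N; ++j) vm_out(is, j) = S[(size_t)j * N_STATE + S_V];
      ++is;
    }
    if (k % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  // commit activations still in progress at the end of the run
  for (int j = 0; j < N; ++j)
    if (excited[j]) act[j].push_back(best_t[j]);

  NumericMatrix fin(N_STATE, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N_STATE; ++i)
      fin(i, j) = S[(size_t)j * N_STATE + i];

  List act_out(N);
  for (int j = 0; j < N; ++j) act_out[j] = wrap(act[j]);

  double vmax = -1e30;
  for (int j = 0; j < N; ++j)
    if (fin(S_V, j) > vmax) vmax = fin(S_V, j);

  return List::create(
    _["t"] = t_out, _["vm"] = vm_out, _["activations"] = act_out,
    _["final_states"] = fin, _["diverged"] = diverged,
    _["t_diverged"] = t_div, _["node_diverged"] = node_div,
    _["max_vm_final"] = vmax);
}
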