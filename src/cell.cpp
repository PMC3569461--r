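#include <Rcpp.h>
#include "nygren.h"
using namespace Rcpp;
using namespace nyg;

// Single-cell pacing driver.  A train of n_beats rectangular stimuli
// (stim_amp pA, stim_dur ms) at cycle length bcl, integrated at fixed dt with
// Rush-Larsen gates.  Vm is recorded every record_dt ms; optionally the full
// state vector is recorded too (used for phase-distributed ring initiation).
// [[Rcpp::export]]
List cpp_pace_cell(NumericVector par, int n_beats, double bcl,
                   double stim_amp, double stim_dur, double dt,
                   double record_dt, Nullable<NumericVector> state0,
                   bool record_states, double t_extra) {
  NygPar p = parFromVector(REAL(par));
  RateTables T;
  T.build(p, dt);

  double s[N_STATE];
  if (state0.isNotNull()) {
    NumericVector s0(state0);
    if (s0.size() != N_STATE) stop("state vector must have %d entries", N_STATE);
    for (int i = 0; i < N_STATE; ++i) s[i] = s0[i];
  } else {
    initState(s);
  }

  double t_end = n_beats * bcl + t_extra;
  long n_steps = (long)std::llround(t_end / dt);
  long rec_every = (long)std::llround(record_dt / dt);
  if (rec_every < 1) rec_every = 1;
  long n_rec = n_steps / rec_every + 1;

  NumericVector t_out(n_rec), v_out(n_rec), dvdt_out(n_rec);
  NumericMatrix st_out = record_states ? NumericMatrix(N_STATE, n_rec)
                                       : NumericMatrix(0, 0);
  long ir = 0;
  t_out[0] = 0.0; v_out[0] = s[S_V]; dvdt_out[0] = 0.0;
  if (record_states) for (int i = 0; i < N_STATE; ++i) st_out(i, 0) = s[i];
  ir = 1;

  bool diverged = false;
  double t_div = NA_REAL;
  SlowCache sc;
  long n_upd = (long)std::llround(0.25 / dt);
  if (n_upd < 1) n_upd = 1;
  for (long k = 0; k < n_steps; ++k) {
    double t = k * dt;
    double istim = 0.0;
    if (n_beats > 0) {
      long beat = (long)(t / bcl);
      double phase = t - beat * bcl;
      if (beat < n_beats && phase < stim_dur) istim = stim_amp;
    }
    if (k % n_upd == 0) refreshSlow(s, sc);
    double dv = cellStep(s, p, T, sc, istim, dt);
    if (!std::isfinite(s[S_V]) || std::fabs(s[S_V]) > 1000.0) {
      diverged = true; t_div = t;
      break;
    }
    if ((k + 1) % rec_every == 0 && ir < n_rec) {
      t_out[ir] = (k + 1) * dt;
      v_out[ir] = s[S_V];
      dvdt_out[ir] = dv;
      if (record_states) for (int i = 0; i < N_STATE; ++i) st_out(i, ir) = s[i];
      ++ir;
    }
    if (k % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector fin(N_STATE);
  for (int i = 0; i < N_STATE; ++i) fin[i] = s[i];
  List out = List::create(
    _["t"] = t_out, _["vm"] = v_out, _["dvdt"] = dvdt_out,
    _["final_state"] = fin, _["diverged"] = diverged, _["t_diverged"] = t_div);
  if (record_states) out["states"] = st_out;
  return out;
}

// Advance one cell n steps under a constant stimulus current.
// [[Rcpp::export]]
List cpp_step_cell(NumericVector par, NumericVector state, double istim,
                   double dt, int n) {
  NygPar p = parFromVector(REAL(par));
  RateTables T;
  T.build(p, dt);
  if (state.size() != N_STATE) stop("state vector must have %d entries", N_STATE);
  double s[N_STATE];
  for (int i = 0; i < N_STATE; ++i) s[i] = state[i];
  bool diverged = false;
  double dv = 0.0;
  SlowCache sc;
  int n_upd = (int)std::llround(0.25 / dt);
  if (n_upd < 1) n_upd = 1;
  for (int k = 0; k < n; ++k) {
    if (k % n_upd == 0) refreshSlow(s, sc);
    dv = cellStep(s, p, T, sc, istim, dt);
    if (!std::isfinite(s[S_V]) || std::fabs(s[S_V]) > 1000.0) {
      diverged = true;
      break;
    }
  }
  NumericVector out(N_STATE);
  for (int i = 0; i < N_STATE; ++i) out[i] = s[i];
  return List::create(_["state"] = out, _["dvdt"] = dv, _["diverged"] = diverged);
}

// [[Rcpp::export]]
NumericVector cpp_initial_state() {
  NumericVector s(N_STATE);
  initState(REAL(s));
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_state_names() {
  const char* nm[] = {"Vm", "m", "h1", "h2", "dL", "fL1", "fL2", "r", "s",
                      "rsus", "ssus", "n", "pa", "Nai", "Ki", "Cai", "Cad",
                      "Nac", "Kc", "Cac", "OC", "OTC", "OTMgC", "OTMgMg",
                      "F1", "F2", "Caup", "Carel", "OCalse"};
  return CharacterVector(nm, nm + N_STATE);
}
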