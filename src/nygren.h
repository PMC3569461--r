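#ifndef ATRIASIM_NYGREN_H
#define ATRIASIM_NYGREN_H

// Nygren et al. human atrial action-potential model, restated in ms / mV / pA / mM
// units (the original formulation uses seconds).  Regional heterogeneity and
// chronic-AF remodeling enter exclusively through NygPar: four maximal
// conductances, one I_CaL inactivation time-constant scale and two
// steady-state-curve shifts.  Everything else is fixed at published values.

#include <cmath>
#include <vector>

namespace nyg {

// ---- fixed physical constants -------------------------------------------
const double R_GAS = 8314.0;     // mJ mol^-1 K^-1
const double TEMP  = 306.15;     // K
const double FDAY  = 96487.0;    // C mol^-1
const double FRT   = FDAY / (R_GAS * TEMP);  // 1/mV
const double CM    = 50.0;       // pF, specific membrane capacitance

// cell compartment volumes (nL) and cleft diffusion time constants (ms)
const double VOL_I   = 0.005884;
const double VOL_D   = 0.02 * VOL_I;
const double VOL_C   = 0.000800224;
const double VOL_UP  = 0.0003969;
const double VOL_REL = 0.0000441;
const double TAU_NA  = 14300.0;
const double TAU_K   = 10000.0;
const double TAU_CA  = 24700.0;
const double NA_B = 130.0, K_B = 5.4, CA_B = 1.8;   // bulk bath (mM)
const double MG_I = 2.5;

// fixed current parameters
const double P_NA     = 0.0016;     // nL/s, I_Na permeability (GHK form)
const double G_SUS    = 2.75;       // nS
const double G_KS     = 1.0;        // nS
const double G_B_NA   = 0.060599;   // nS
const double G_B_CA   = 0.078681;   // nS
const double E_CA_APP = 60.0;       // mV
const double K_CA     = 0.025;      // mM
const double I_NAK_MAX = 70.8253;   // pA
const double K_NAK_K  = 1.0;        // mM
const double K_NAK_NA = 11.0;       // mM
const double I_CAP_MAX = 4.0;       // pA
const double K_CAP    = 0.0002;     // mM
const double K_NACA   = 0.0374842;  // pA mM^-4
const double GAMMA_NACA = 0.45;
const double D_NACA   = 0.0003;     // mM^-4
const double PHI_NA_EN = -1.68;     // pA, electroneutral Na influx
const double I_UP_MAX = 2800.0;     // pA
const double K_CYCA   = 0.0003;     // mM
const double K_SRCA   = 0.5;        // mM
const double K_XCS    = 0.4;
const double TAU_TR_S = 0.01;       // s (kept in s: converts mM to pA)
const double TAU_DI_S = 0.01;       // s
const double ALPHA_REL = 200000.0;  // pA/mM
const double R_RECOV  = 0.815;      // 1/s
const double K_REL_I  = 0.0003;     // mM
const double K_REL_D  = 0.003;      // mM

// ---- state layout --------------------------------------------------------
enum StateIdx {
  S_V = 0, S_M, S_H1, S_H2, S_DL, S_FL1, S_FL2, S_R, S_S,
  S_RSUS, S_SSUS, S_N, S_PA,
  S_NAI, S_KI, S_CAI, S_CAD, S_NAC, S_KC, S_CAC,
  S_OC, S_OTC, S_OTMGC, S_OTMGMG, S_F1, S_F2, S_CAUP, S_CAREL, S_OCALSE,
  N_STATE
};
const int N_GATE = 12;  // S_M .. S_PA inclusive

// resting initial conditions (original publication's quiescent state)
inline void initState(double* s) {
  s[S_V] = -74.2525;
  s[S_M] = 0.0032017; s[S_H1] = 0.8814; s[S_H2] = 0.8742;
  s[S_DL] = 1.3005e-5; s[S_FL1] = 0.9986; s[S_FL2] = 0.9986;
  s[S_R] = 0.0010678; s[S_S] = 0.949;
  s[S_RSUS] = 1.5949e-4; s[S_SSUS] = 0.9912;
  s[S_N] = 0.0048357; s[S_PA] = 0.0001;
  s[S_NAI] = 8.5547; s[S_KI] = 129.435; s[S_CAI] = 6.729e-5; s[S_CAD] = 7.2495e-5;
  s[S_NAC] = 130.011; s[S_KC] = 5.3581; s[S_CAC] = 1.8147;
  s[S_OC] = 0.0275; s[S_OTC] = 0.0133; s[S_OTMGC] = 0.1961; s[S_OTMGMG] = 0.7094;
  s[S_F1] = 0.2883; s[S_F2] = 0.0028;
  s[S_CAUP] = 0.6646; s[S_CAREL] = 0.6465; s[S_OCALSE] = 0.4369;
}

// ---- variant parameters --------------------------------------------------
struct NygPar {
  double g_t;        // nS
  double g_cal;      // nS
  double g_kr;       // nS
  double g_k1;       // nS
  double tau_f1_scale;  // multiplier on fast I_CaL inactivation tau
  double r_shift;    // mV, I_t activation curve shift (+ = depolarizing)
  double h_shift;    // mV, I_Na inactivation curve shift (+ = depolarizing)
};

// ---- voltage-dependent gate rates ---------------------------------------
// inf and tau (ms) for each gate at voltage v, given variant kinetics
inline void gateRates(int g, double v, const NygPar& p, double& inf, double& tau) {
  double x;
  switch (g) {
  case 0:  // m
    inf = 1.0 / (1.0 + std::exp(-(v + 27.12) / 8.21));
    x = (v + 25.57) / 28.8;
    tau = 0.042 * std::exp(-x * x) + 0.024;
    break;
  case 1:  // h1
    inf = 1.0 / (1.0 + std::exp((v - p.h_shift + 63.6) / 5.3));
    tau = 30.0 / (1.0 + std::exp((v + 35.1) / 3.2)) + 0.3;
    break;
  case 2:  // h2
    inf = 1.0 / (1.0 + std::exp((v - p.h_shift + 63.6) / 5.3));
    tau = 120.0 / (1.0 + std::exp((v + 35.1) / 3.2)) + 3.0;
    break;
  case 3:  // d_L
    inf = 1.0 / (1.0 + std::exp(-(v + 9.0) / 5.8));
    x = (v + 35.0) / 30.0;
    tau = 2.7 * std::exp(-x * x) + 2.0;
    break;
  case 4:  // f_L1
    inf = 1.0 / (1.0 + std::exp((v + 27.4) / 7.1));
    x = (v + 40.0) / 14.4;
    tau = (161.0 * std::exp(-x * x) + 10.0) * p.tau_f1_scale;
    break;
  case 5:  // f_L2
    inf = 1.0 / (1.0 + std::exp((v + 27.4) / 7.1));
    x = (v + 40.0) / 14.2;
    tau = 1332.3 * std::exp(-x * x) + 62.6;
    break;
  case 6:  // r (I_t activation)
    inf = 1.0 / (1.0 + std::exp(-(v - p.r_shift - 1.0) / 11.0));
    x = v / 30.0;
    tau = 3.5 * std::exp(-x * x) + 1.5;
    break;
  case 7:  // s (I_t inactivation)
    inf = 1.0 / (1.0 + std::exp((v + 40.5) / 11.5));
    x = (v + 52.45) / 14.97;
    tau = 481.2 * std::exp(-x * x) + 14.14;
    break;
  case 8:  // r_sus
    inf = 1.0 / (1.0 + std::exp(-(v + 4.3) / 8.0));
    tau = 9.0 / (1.0 + std::exp((v + 5.0) / 12.0)) + 0.5;
    break;
  case 9:  // s_sus
    inf = 0.4 / (1.0 + std::exp((v + 20.0) / 10.0)) + 0.6;
    tau = 47.0 / (1.0 + std::exp((v + 60.0) / 10.0)) + 300.0;
    break;
  case 10: // n (I_Ks)
    inf = 1.0 / (1.0 + std::exp(-(v - 19.9) / 12.7));
    tau = 700.0;
    break;
  default: // 11: p_a (I_Kr)
    inf = 1.0 / (1.0 + std::exp(-(v + 15.0) / 6.0));
    x = (v + 20.1376) / 22.1996;
    tau = 31.18 + 217.18 * std::exp(-x * x);
    break;
  }
}

// ---- precomputed rate tables for a fixed time step ----------------------
// Linear interpolation over V in [-150, 150] mV at 0.05 mV; Rush-Larsen gate
// update needs inf(V) and 1 - exp(-dt/tau(V)); three pure-voltage exponentials
// used by I_Na (GHK) and I_NaCa are tabulated alongside.
struct RateTables {
  static const int NV = 6001;
  double v0, dv;
  std::vector<double> inf;   // N_GATE * NV
  std::vector<double> rl;    // N_GATE * NV, 1 - exp(-dt/tau)
  std::vector<double> e1;    // exp(V*FRT)
  std::vector<double> eg;    // exp(gamma*V*FRT)
  std::vector<double> egm;   // exp((gamma-1)*V*FRT)
  std::vector<double> e15;   // exp(1.5*V*FRT), inward-rectifier gate
  std::vector<double> pik;   // instantaneous I_Kr inactivation p_i(V)

  void build(const NygPar& p, double dt) {
    v0 = -150.0; dv = 300.0 / (NV - 1);
    inf.assign(N_GATE * NV, 0.0);
    rl.assign(N_GATE * NV, 0.0);
    e1.assign(NV, 0.0); eg.assign(NV, 0.0); egm.assign(NV, 0.0);
    e15.assign(NV, 0.0); pik.assign(NV, 0.0);
    for (int i = 0; i < NV; ++i) {
      double v = v0 + i * dv;
      for (int g = 0; g < N_GATE; ++g) {
        double gi, gt;
        gateRates(g, v, p, gi, gt);
        inf[g * NV + i] = gi;
        rl[g * NV + i] = 1.0 - std::exp(-dt / gt);
      }
      e1[i] = std::exp(v * FRT);
      eg[i] = std::exp(GAMMA_NACA * v * FRT);
      egm[i] = std::exp((GAMMA_NACA - 1.0) * v * FRT);
      e15[i] = std::exp(1.5 * v * FRT);
      pik[i] = 1.0 / (1.0 + std::exp((v + 55.0) / 24.0));
    }
  }
  inline void locate(double v, int& i, double& w) const {
    double u = (v - v0) / dv;
    // NaN-safe clamp: a diverging state must not index out of bounds
    if (!(u >= 0.0)) u = 0.0;
    if (u > NV - 1.001) u = NV - 1.001;
    i = (int)u;
    w = u - i;
  }
  inline double lin(const std::vector<double>& t, int off, int i, double w) const {
    return t[off + i] * (1.0 - w) + t[off + i + 1] * w;
  }
};

// ---- slowly varying per-cell quantities ----------------------------------
// Reversal potentials and concentration powers change on the seconds scale;
// they are refreshed every ~0.25 ms rather than every 0.02 ms step.
struct SlowCache {
  double ek, ena, eca;   // reversal potentials, mV
  double powkc;          // Kc^0.4457 (inward-rectifier conductance factor)
  double nai15;          // Nai^1.5 (Na/K pump)
  double ik1fac;         // exp(1.5*(3.6 - ek)*FRT)
};

inline void refreshSlow(const double* s, SlowCache& c) {
  c.ek  = std::log(s[S_KC] / s[S_KI]) / FRT;
  c.ena = std::log(s[S_NAC] / s[S_NAI]) / FRT;
  c.eca = 0.5 * std::log(s[S_CAC] / s[S_CAI]) / FRT;
  c.powkc = std::pow(s[S_KC], 0.4457);
  c.nai15 = s[S_NAI] * std::sqrt(s[S_NAI]);
  c.ik1fac = std::exp(1.5 * (3.6 - c.ek) * FRT);
}

const double KNA15 = 36.48287269390939;  // 11^1.5

// ---- one integration step ------------------------------------------------
// Rush-Larsen for the 12 gates, forward Euler for Vm and concentrations.
// istim: depolarizing stimulus current in pA (>0 depolarizes).
// Returns dV/dt (mV/ms) before the step is applied (for activation detection).
inline double cellStep(double* s, const NygPar& p, const RateTables& T,
                       const SlowCache& c, double istim, double dt) {
  double v = s[S_V];
  int ti; double tw;
  T.locate(v, ti, tw);

  double ek = c.ek, ena = c.ena, eca = c.eca;

  // I_Na (GHK): exp((V-E_Na)FRT) = exp(V*FRT) * Nai/Nac
  double ve = (std::fabs(v) < 1e-4) ? 1e-4 : v;
  double ex = T.lin(T.e1, 0, ti, tw);
  double ina = P_NA * s[S_M] * s[S_M] * s[S_M] * (0.9 * s[S_H1] + 0.1 * s[S_H2]) *
               s[S_NAC] * ve * FDAY * FRT *
               (ex * s[S_NAI] / s[S_NAC] - 1.0) / (ex - 1.0);

  double fca = s[S_CAD] / (s[S_CAD] + K_CA);
  double ical = p.g_cal * s[S_DL] * (fca * s[S_FL1] + (1.0 - fca) * s[S_FL2]) *
                (v - E_CA_APP);

  double it   = p.g_t * s[S_R] * s[S_S] * (v - ek);
  double isus = G_SUS * s[S_RSUS] * s[S_SSUS] * (v - ek);
  double ik1  = p.g_k1 * c.powkc * (v - ek) /
                (1.0 + T.lin(T.e15, 0, ti, tw) * c.ik1fac);
  double ikr  = p.g_kr * s[S_PA] * T.lin(T.pik, 0, ti, tw) * (v - ek);
  double iks  = G_KS * s[S_N] * (v - ek);

  double ibna = G_B_NA * (v - ena);
  double ibca = G_B_CA * (v - eca);

  double inak = I_NAK_MAX * s[S_KC] / (s[S_KC] + K_NAK_K) *
                c.nai15 / (c.nai15 + KNA15) *
                (v + 150.0) / (v + 200.0);

  double icap = I_CAP_MAX * s[S_CAI] / (s[S_CAI] + K_CAP);

  double nai3 = s[S_NAI] * s[S_NAI] * s[S_NAI];
  double nac3 = s[S_NAC] * s[S_NAC] * s[S_NAC];
  double inaca = K_NACA *
      (nai3 * s[S_CAC] * T.lin(T.eg, 0, ti, tw) -
       nac3 * s[S_CAI] * T.lin(T.egm, 0, ti, tw)) /
      (1.0 + D_NACA * (nac3 * s[S_CAI] + nai3 * s[S_CAC]));

  // sarcoplasmic reticulum fluxes (pA)
  double iup = I_UP_MAX * (s[S_CAI] / K_CYCA - K_XCS * K_XCS * s[S_CAUP] / K_SRCA) /
               ((s[S_CAI] + K_CYCA) / K_CYCA + K_XCS * (s[S_CAUP] + K_SRCA) / K_SRCA);
  double itr = (s[S_CAUP] - s[S_CAREL]) * 2.0 * FDAY * VOL_REL / TAU_TR_S;
  double f2r = s[S_F2] / (s[S_F2] + 0.25);
  double irel = ALPHA_REL * f2r * f2r * (s[S_CAREL] - s[S_CAI]);
  double idi = (s[S_CAD] - s[S_CAI]) * 2.0 * FDAY * VOL_D / TAU_DI_S;

  // RyR activation / SERCA machinery (rates per second)
  double acti = s[S_CAI] / (s[S_CAI] + K_REL_I);
  double actd = s[S_CAD] / (s[S_CAD] + K_REL_D);
  double acti4 = acti * acti * acti * acti;
  double actd4 = actd * actd * actd * actd;
  double ract = 203.8 * (acti4 + actd4);
  double rinact = 33.96 + 339.6 * acti4;

  // Ca buffering (per ms)
  double dOC = (200000.0 * s[S_CAI] * (1.0 - s[S_OC]) - 476.0 * s[S_OC]) * 1e-3;
  double dOTC = (78400.0 * s[S_CAI] * (1.0 - s[S_OTC]) - 392.0 * s[S_OTC]) * 1e-3;
  double dOTMgC = (200000.0 * s[S_CAI] * (1.0 - s[S_OTMGC] - s[S_OTMGMG]) -
                   6.6 * s[S_OTMGC]) * 1e-3;
  double dOTMgMg = (2000.0 * MG_I * (1.0 - s[S_OTMGC] - s[S_OTMGMG]) -
                    666.0 * s[S_OTMGMG]) * 1e-3;
  double dOCalse = (480.0 * s[S_CAREL] * (1.0 - s[S_OCALSE]) -
                    400.0 * s[S_OCALSE]) * 1e-3;

  double itot = ina + ical + it + isus + ik1 + ikr + iks +
                ibna + ibca + inak + icap + inaca - istim;
  double dv = -itot / CM;  // mV/ms

  // concentration derivatives (mM/ms); currents in pA, volumes nL
  double c_i = 1e-3 / (VOL_I * FDAY);
  double c_c = 1e-3 / (VOL_C * FDAY);
  double dNai = -(ina + ibna + 3.0 * inak + 3.0 * inaca + PHI_NA_EN) * c_i;
  double dKi  = -(it + isus + ik1 + ikr + iks - 2.0 * inak) * c_i;
  double dCad = -(ical + idi) * 1e-3 / (2.0 * VOL_D * FDAY);
  double dCai = -(-idi + ibca + icap - 2.0 * inaca + iup - irel) * 1e-3 /
                (2.0 * VOL_I * FDAY) -
                (0.045 * dOC + 0.08 * dOTC + 0.16 * dOTMgC);
  double dNac = (NA_B - s[S_NAC]) / TAU_NA +
                (ina + ibna + 3.0 * inak + 3.0 * inaca + PHI_NA_EN) * c_c;
  double dKc  = (K_B - s[S_KC]) / TAU_K +
                (it + isus + ik1 + ikr + iks - 2.0 * inak) * c_c;
  double dCac = (CA_B - s[S_CAC]) / TAU_CA +
                (ical + ibca + icap - 2.0 * inaca) * 1e-3 / (2.0 * VOL_C * FDAY);
  double dCaup = (iup - itr) * 1e-3 / (2.0 * VOL_UP * FDAY);
  double dCarel = (itr - irel) * 1e-3 / (2.0 * VOL_REL * FDAY) - 31.0 * dOCalse;
  double dF1 = (R_RECOV * (1.0 - s[S_F1] - s[S_F2]) - ract * s[S_F1]) * 1e-3;
  double dF2 = (ract * s[S_F1] - rinact * s[S_F2]) * 1e-3;

  // Rush-Larsen gate updates from the tables
  const int NV = RateTables::NV;
  for (int g = 0; g < N_GATE; ++g) {
    int off = g * NV;
    double gi = T.lin(T.inf, off, ti, tw);
    double ga = T.lin(T.rl, off, ti, tw);
    double& gv = s[S_M + g];
    gv += (gi - gv) * ga;
  }

  s[S_V] += dt * dv;
  s[S_NAI] += dt * dNai;  s[S_KI] += dt * dKi;
  s[S_CAI] += dt * dCai;  s[S_CAD] += dt * dCad;
  s[S_NAC] += dt * dNac;  s[S_KC] += dt * dKc;  s[S_CAC] += dt * dCac;
  s[S_OC] += dt * dOC;    s[S_OTC] += dt * dOTC;
  s[S_OTMGC] += dt * dOTMgC;  s[S_OTMGMG] += dt * dOTMgMg;
  s[S_F1] += dt * dF1;    s[S_F2] += dt * dF2;
  s[S_CAUP] += dt * dCaup;  s[S_CAREL] += dt * dCarel;
  s[S_OCALSE] += dt * dOCalse;

  return dv;
}

inline NygPar parFromVector(const double* p) {
  NygPar out;
  out.g_t = p[0]; out.g_cal = p[1]; out.g_kr = p[2]; out.g_k1 = p[3];
  out.tau_f1_scale = p[4]; out.r_shift = p[5]; out.h_shift = p[6];
  return out;
}

}  // namespace nyg

#endif
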