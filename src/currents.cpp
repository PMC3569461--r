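#include <Rcpp.h>
#include "nygren.h"
using namespace Rcpp;
using namespace nyg;

// [[Rcpp::export]]
NumericVector cpp_currents(NumericVector par, NumericVector state) {
  NygPar p = parFromVector(REAL(par));
  const double* s = REAL(state);
  SlowCache c; refreshSlow(s, c);
  double v = s[S_V];
  double ek = c.ek, ena = c.ena, eca = c.eca;
  double ve = (std::fabs(v) < 1e-4) ? 1e-4 : v;
  double ex = std::exp(ve * FRT);
  double ina = P_NA * s[S_M]*s[S_M]*s[S_M]*(0.9*s[S_H1]+0.1*s[S_H2]) *
               s[S_NAC]*ve*FDAY*FRT*(ex*s[S_NAI]/s[S_NAC]-1.0)/(ex-1.0);
  double fca = s[S_CAD]/(s[S_CAD]+K_CA);
  double ical = p.g_cal*s[S_DL]*(fca*s[S_FL1]+(1.0-fca)*s[S_FL2])*(v-E_CA_APP);
  double it   = p.g_t*s[S_R]*s[S_S]*(v-ek);
  double isus = G_SUS*s[S_RSUS]*s[S_SSUS]*(v-ek);
  double ik1  = p.g_k1*std::pow(s[S_KC],0.4457)*(v-ek)/(1.0+std::exp(1.5*(v-ek+3.6)*FRT));
  double ikr  = p.g_kr*s[S_PA]*(1.0/(1.0+std::exp((v+55.0)/24.0)))*(v-ek);
  double iks  = G_KS*s[S_N]*(v-ek);
  double ibna = G_B_NA*(v-ena), ibca = G_B_CA*(v-eca);
  double nai15 = s[S_NAI]*std::sqrt(s[S_NAI]);
  double inak = I_NAK_MAX*s[S_KC]/(s[S_KC]+K_NAK_K)*nai15/(nai15+K_NAK_NA*std::sqrt(K_NAK_NA))*(v+150.0)/(v+200.0);
  double icap = I_CAP_MAX*s[S_CAI]/(s[S_CAI]+K_CAP);
  double nai3 = s[S_NAI]*s[S_NAI]*s[S_NAI], nac3 = s[S_NAC]*s[S_NAC]*s[S_NAC];
  double inaca = K_NACA*(nai3*s[S_CAC]*std::exp(GAMMA_NACA*v*FRT) -
                 nac3*s[S_CAI]*std::exp((GAMMA_NACA-1.0)*v*FRT)) /
                 (1.0+D_NACA*(nac3*s[S_CAI]+nai3*s[S_CAC]));
  return NumericVector::create(_["ina"]=ina,_["ical"]=ical,_["it"]=it,_["isus"]=isus,
    _["ik1"]=ik1,_["ikr"]=ikr,_["iks"]=iks,_["ibna"]=ibna,_["ibca"]=ibca,
    _["inak"]=inak,_["icap"]=icap,_["inaca"]=inaca,_["ek"]=ek);
}
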