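// Common-pool coupled-clock sinoatrial-node cell model: membrane clock
// (I_CaL, I_CaT, I_Kr, I_Ks, I_to, I_sus, I_f, I_st, I_bNa, I_NaK, I_NCX,
// I_KACh) coupled to an SR Ca clock (SERCA uptake, RyR release, two SR
// compartments, cytosolic/submembrane buffering).
//
// Units: time ms, voltage mV, current pA, conductance-density nS/pF,
// capacitance pF, concentration mM, volume pL.  With these units
// I[pA] / (2*F[C/mol] * V[pL]) is directly mM/ms.
//
// The fixed-step explicit (forward-Euler) integrator is the canonical path;
// voltage-dependent gating rates are tabulated on a fine Vm grid and linearly
// interpolated inside the integrator.  cm_derivs() always evaluates the exact
// expressions and is the reference for tests.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- parameters
enum ParIdx {
  P_CM, P_GCAL, P_GCAT, P_GKR, P_GKS, P_GTO, P_GSUS, P_GIF, P_GST, P_GBNA,
  P_INAKMAX, P_KNCX, P_DNCX, P_GKACH, P_EIFSHIFT,
  P_PUP, P_KUP, P_TDIFCA, P_TTR, P_KS,
  P_KOCA, P_KOM, P_KICA, P_KIM, P_EC50SR, P_MAXSR, P_MINSR, P_HSR,
  P_TCTOT, P_TMCTOT, P_CMTOT, P_CQTOT,
  P_KFTC, P_KBTC, P_KFTMC, P_KBTMC, P_KFTMM, P_KBTMM,
  P_KFCM, P_KBCM, P_KFCQ, P_KBCQ, P_MGI,
  P_VI, P_VSUB, P_VJSR, P_VNSR,
  P_NAI, P_NAO, P_KI, P_KO, P_CAO,
  P_ECAL, P_ECAT, P_EST, P_TEMP, P_KMFCA, P_ALPHAFCA, P_KMKP, P_KMNAP,
  NPAR
};

static const char* PAR_NAMES[NPAR] = {
  "C_m", "g_CaL", "g_CaT", "g_Kr", "g_Ks", "g_to", "g_sus", "g_if", "g_st",
  "g_bNa", "i_NaK_max", "k_NCX", "d_NCX", "g_KACh", "E_if_shift",
  "P_up", "K_up", "tau_dif_Ca", "tau_tr", "k_s",
  "k_oCa", "k_om", "k_iCa", "k_im", "ec50_SR", "max_SR", "min_SR", "h_SR",
  "TC_tot", "TMC_tot", "CM_tot", "CQ_tot",
  "kf_TC", "kb_TC", "kf_TMC", "kb_TMC", "kf_TMM", "kb_TMM",
  "kf_CM", "kb_CM", "kf_CQ", "kb_CQ", "Mg_i",
  "V_i", "V_sub", "V_jSR", "V_nSR",
  "Na_i", "Na_o", "K_i", "K_o", "Ca_o",
  "E_CaL", "E_CaT", "E_st", "temperature", "Km_fCa", "alpha_fCa",
  "Km_Kp", "Km_Nap"
};

// --------------------------------------------------------------------- state
enum StIdx {
  S_VM, S_DL, S_FL, S_FCA, S_DT, S_FT, S_PAF, S_PAS, S_PIY, S_N,
  S_Q, S_R, S_Y, S_QA, S_QI,
  S_CAI, S_CASUB, S_CANSR, S_CAJSR,
  S_RR, S_RO, S_RI,
  S_FCMI, S_FCMS, S_FTC, S_FTMC, S_FTMM, S_FCQ,
  NSTATE
};

static const char* STATE_NAMES[NSTATE] = {
  "V_m", "d_L", "f_L", "f_Ca", "d_T", "f_T", "pa_F", "pa_S", "pi_y", "n",
  "q", "r", "y", "q_a", "q_i",
  "Ca_i", "Ca_sub", "Ca_nSR", "Ca_jSR",
  "R_ryr", "O_ryr", "I_ryr",
  "f_CMi", "f_CMs", "f_TC", "f_TMC", "f_TMM", "f_CQ"
};

enum CurIdx {
  C_ICAL, C_ICAT, C_IKR, C_IKS, C_ITO, C_ISUS, C_IF, C_IST, C_IBNA,
  C_INAK, C_INCX, C_IKACH, C_ITOT, NCUR
};
static const char* CUR_NAMES[NCUR] = {
  "I_CaL", "I_CaT", "I_Kr", "I_Ks", "I_to", "I_sus", "I_f", "I_st", "I_bNa",
  "I_NaK", "I_NCX", "I_KACh", "I_tot"
};

static const double FARADAY = 96485.3415; // C/mol
static const double RGAS = 8314.472;      // mJ/(mol K)

// Voltage-dependent quantities (gating steady states / time constants and
// the voltage factors of NCX, NaK, KACh).
struct VDep {
  double dLinf, tdL, fLinf, tfL;
  double dTinf, tdT, fTinf, tfT;
  double painf, tpaF, tpaS, piinf, tpi;
  double ninf, tn;
  double qinf, tq, rinf, tr;
  double yinf, ty;
  double qainf, tqa, qiinf, tqi;
  double ncx_e1, ncx_e2;  // exp(+0.5 V/ET), exp(-0.5 V/ET)
  double f_nak;           // voltage factor of I_NaK
  double f_kach;          // rectification factor of I_KACh
  // Rush-Larsen factors 1 - exp(-dt/tau), filled at table-build time (0 in
  // exact evaluation; unused by cm_derivs)
  double rl_dL, rl_fL, rl_dT, rl_fT, rl_paF, rl_paS, rl_piy, rl_n,
         rl_q, rl_r, rl_y, rl_qa, rl_qi;
};
#define NVDEP (sizeof(VDep) / sizeof(double))

static inline double sx(double v, double v0, double k) {
  // rising sigmoid: 1/(1+exp(-(v - v0)/k))
  return 1.0 / (1.0 + std::exp(-(v - v0) / k));
}

static void vdep_exact(double v, const double* p, VDep* g) {
  const double ET = RGAS * p[P_TEMP] / FARADAY;
  const double ENa = ET * std::log(p[P_NAO] / p[P_NAI]);
  const double EK  = ET * std::log(p[P_KO] / p[P_KI]);

  // I_CaL activation/inactivation
  g->dLinf = sx(v, -13.5, 6.0);
  {
    // alpha = -0.02839 (v+35)/(exp(-(v+35)/2.5)-1) - 0.0849 v/(exp(-v/4.8)-1)
    // beta  =  0.01143 (v-5)/(exp((v-5)/2.5)-1); singular points -> limits
    double d1 = -(v + 35.0) / 2.5;
    double t1 = (std::fabs(d1) < 1e-6) ? -2.5 : (v + 35.0) / (std::exp(d1) - 1.0);
    double d2 = -v / 4.8;
    double t2 = (std::fabs(d2) < 1e-6) ? -4.8 : v / (std::exp(d2) - 1.0);
    double a = -0.02839 * t1 - 0.0849 * t2;
    double d3 = (v - 5.0) / 2.5;
    double t3 = (std::fabs(d3) < 1e-6) ? 2.5 : (v - 5.0) / (std::exp(d3) - 1.0);
    double b = 0.01143 * t3;
    g->tdL = 1.0 / (a + b);
  }
  g->fLinf = sx(v, -35.0, -7.3);
  g->tfL = 44.3 + 230.0 * std::exp(-std::pow((v + 36.0) / 10.0, 2));

  // I_CaT
  g->dTinf = sx(v, -26.3, 6.0);
  g->tdT = 1.0 / (1.068 * std::exp((v + 26.3) / 30.0) +
                  1.068 * std::exp(-(v + 26.3) / 30.0));
  g->fTinf = sx(v, -61.7, -5.6);
  g->tfT = 1.0 / (0.0153 * std::exp(-(v + 61.7) / 83.3) +
                  0.015 * std::exp((v + 61.7) / 15.38));

  // I_Kr
  g->painf = sx(v, -14.2, 10.6);
  g->tpaF = 846.55354 / (37.2 * std::exp((v - 9.0) / 15.9) +
                         0.96 * std::exp(-(v - 9.0) / 22.5));
  g->tpaS = 846.55354 / (4.2 * std::exp((v - 9.0) / 17.0) +
                         0.15 * std::exp(-(v - 9.0) / 21.6));
  g->piinf = sx(v, -28.6, -17.1);
  g->tpi = 1000.0 / (100.0 * std::exp(-v / 54.645) +
                     656.0 * std::exp(v / 106.157));

  // I_Ks (n^2 gating)
  {
    double an = 0.014 / (1.0 + std::exp(-(v - 40.0) / 9.0));
    double bn = 0.001 * std::exp(-v / 45.0);
    g->ninf = an / (an + bn);
    g->tn = 1.0 / (an + bn);
  }

  // I_to / I_sus
  g->qinf = sx(v, -49.0, -13.0);
  g->tq = 6.06 + 39.102 / (0.57 * std::exp(-0.08 * (v + 44.0)) +
                           0.065 * std::exp(0.1 * (v + 45.93)));
  g->rinf = sx(v, 19.3, 15.0);
  g->tr = 2.75 + 14.40516 / (1.037 * std::exp(0.09 * (v + 30.61)) +
                             0.369 * std::exp(-0.12 * (v + 23.84)));

  // I_f (activation curve shifted by E_if_shift, e.g. under carbachol)
  {
    double vy = v - p[P_EIFSHIFT];
    g->yinf = sx(vy, -64.0, -13.5);
    g->ty = 715.66 / (std::exp(-(vy + 386.9) / 45.302) +
                      std::exp((vy - 73.08) / 19.231));
  }

  // I_st
  g->qainf = sx(v, -57.0, 5.0);
  {
    double aqa = 1.0 / (0.15 * std::exp(-v / 11.0) + 0.2 * std::exp(-v / 700.0));
    double bqa = 1.0 / (16.0 * std::exp(v / 8.0) + 15.0 * std::exp(v / 50.0));
    g->tqa = 1.0 / (aqa + bqa);
    double aqi = 0.1504 / (3100.0 * std::exp(v / 13.0) + 700.0 * std::exp(v / 70.0));
    double bqi = 0.1504 / (95.0 * std::exp(-v / 10.0) + 50.0 * std::exp(-v / 700.0)) +
                 0.000229 / (1.0 + std::exp(-v / 5.0));
    g->qiinf = aqi / (aqi + bqi);
    g->tqi = 1.0 / (aqi + bqi);
  }

  // NCX voltage factors (gamma = 0.5)
  g->ncx_e1 = std::exp(0.5 * v / ET);
  g->ncx_e2 = std::exp(-0.5 * v / ET);

  // NaK voltage factor
  g->f_nak = 1.0 / (1.0 + std::exp(-(v - ENa + 110.0) / 20.0));

  // KACh inward rectification
  g->f_kach = 1.0 / (1.0 + std::exp((v - EK - 140.0) / (2.5 * ET)));

  g->rl_dL = g->rl_fL = g->rl_dT = g->rl_fT = g->rl_paF = g->rl_paS =
      g->rl_piy = g->rl_n = g->rl_q = g->rl_r = g->rl_y = g->rl_qa =
      g->rl_qi = 0.0;
}

// ------------------------------------------------------------ lookup table
struct VTab {
  double vmin, vmax, inv_step;
  int n;
  std::vector<double> tab; // n rows x NVDEP cols, row-major
  void build(const double* p, double dt) {
    vmin = -650.0; vmax = 480.0;
    double step = 0.05;
    inv_step = 1.0 / step;
    n = (int)((vmax - vmin) * inv_step) + 1;
    tab.resize((size_t)n * NVDEP);
    VDep g;
    for (int i = 0; i < n; i++) {
      vdep_exact(vmin + i * step, p, &g);
      g.rl_dL = -std::expm1(-dt / g.tdL);
      g.rl_fL = -std::expm1(-dt / g.tfL);
      g.rl_dT = -std::expm1(-dt / g.tdT);
      g.rl_fT = -std::expm1(-dt / g.tfT);
      g.rl_paF = -std::expm1(-dt / g.tpaF);
      g.rl_paS = -std::expm1(-dt / g.tpaS);
      g.rl_piy = -std::expm1(-dt / g.tpi);
      g.rl_n = -std::expm1(-dt / g.tn);
      g.rl_q = -std::expm1(-dt / g.tq);
      g.rl_r = -std::expm1(-dt / g.tr);
      g.rl_y = -std::expm1(-dt / g.ty);
      g.rl_qa = -std::expm1(-dt / g.tqa);
      g.rl_qi = -std::expm1(-dt / g.tqi);
      const double* src = (const double*)&g;
      for (size_t j = 0; j < NVDEP; j++) tab[(size_t)i * NVDEP + j] = src[j];
    }
  }
  inline void eval(double v, VDep* g) const {
    double x = (v - vmin) * inv_step;
    if (x < 0) x = 0;
    if (x > n - 1.000001) x = n - 1.000001;
    int i = (int)x;
    double w = x - i;
    const double* a = &tab[(size_t)i * NVDEP];
    const double* b = a + NVDEP;
    double* dst = (double*)g;
    for (size_t j = 0; j < NVDEP; j++) dst[j] = a[j] + w * (b[j] - a[j]);
  }
};

// ------------------------------------------------------------- derivatives
// i_stim: injected current, pA, positive = depolarizing.
// j_lcr: extra Ca flux into the submembrane space (mM/ms), stochastic-LCR hook.
static void derivs(const double* s, const double* p, const VDep& g,
                   double i_stim, double j_lcr, double* ds, double* cur) {
  const double ET = RGAS * p[P_TEMP] / FARADAY;
  const double ENa = ET * std::log(p[P_NAO] / p[P_NAI]);
  const double EK  = ET * std::log(p[P_KO] / p[P_KI]);
  const double EKs = ET * std::log((p[P_KO] + 0.12 * p[P_NAO]) /
                                   (p[P_KI] + 0.12 * p[P_NAI]));
  const double cm = p[P_CM];
  const double v = s[S_VM];

  // --- membrane currents (pA) ---
  double ical = cm * p[P_GCAL] * (v - p[P_ECAL]) * s[S_DL] * s[S_FL] * s[S_FCA];
  double icat = cm * p[P_GCAT] * (v - p[P_ECAT]) * s[S_DT] * s[S_FT];
  double ikr  = cm * p[P_GKR] * (v - EK) *
                (0.6 * s[S_PAF] + 0.4 * s[S_PAS]) * s[S_PIY];
  double iks  = cm * p[P_GKS] * (v - EKs) * s[S_N] * s[S_N];
  double ito  = cm * p[P_GTO] * (v - EK) * s[S_Q] * s[S_R];
  double isus = cm * p[P_GSUS] * (v - EK) * s[S_R];
  double iff  = cm * p[P_GIF] * s[S_Y] *
                (0.3833 * (v - ENa) + 0.6167 * (v - EK));
  double ist  = cm * p[P_GST] * (v - p[P_EST]) * s[S_QA] * s[S_QI];
  double ibna = cm * p[P_GBNA] * (v - ENa);
  double inak = cm * p[P_INAKMAX] * g.f_nak /
                ((1.0 + std::pow(p[P_KMKP] / p[P_KO], 1.2)) *
                 (1.0 + std::pow(p[P_KMNAP] / p[P_NAI], 1.3)));
  double na3 = p[P_NAI] * p[P_NAI] * p[P_NAI];
  double nao3 = p[P_NAO] * p[P_NAO] * p[P_NAO];
  double incx = cm * p[P_KNCX] *
                (na3 * p[P_CAO] * g.ncx_e1 - nao3 * s[S_CASUB] * g.ncx_e2) /
                (1.0 + p[P_DNCX] * (s[S_CASUB] * nao3 + p[P_CAO] * na3));
  double ikach = cm * p[P_GKACH] * (p[P_KO] / (p[P_KO] + 10.0)) *
                 (v - EK) * g.f_kach;

  double itot = ical + icat + ikr + iks + ito + isus + iff + ist + ibna +
                inak + incx + ikach;

  if (cur) {
    cur[C_ICAL] = ical; cur[C_ICAT] = icat; cur[C_IKR] = ikr;
    cur[C_IKS] = iks; cur[C_ITO] = ito; cur[C_ISUS] = isus;
    cur[C_IF] = iff; cur[C_IST] = ist; cur[C_IBNA] = ibna;
    cur[C_INAK] = inak; cur[C_INCX] = incx; cur[C_IKACH] = ikach;
    cur[C_ITOT] = itot;
  }

  ds[S_VM] = (-itot + i_stim) / cm;

  // --- gating ---
  ds[S_DL]  = (g.dLinf - s[S_DL]) / g.tdL;
  ds[S_FL]  = (g.fLinf - s[S_FL]) / g.tfL;
  {
    double cs = s[S_CASUB] > 0.0 ? s[S_CASUB] : 0.0;
    double fcainf = p[P_KMFCA] / (p[P_KMFCA] + cs);
    double tfca = fcainf / p[P_ALPHAFCA];
    ds[S_FCA] = (fcainf - s[S_FCA]) / tfca;
  }
  ds[S_DT]  = (g.dTinf - s[S_DT]) / g.tdT;
  ds[S_FT]  = (g.fTinf - s[S_FT]) / g.tfT;
  ds[S_PAF] = (g.painf - s[S_PAF]) / g.tpaF;
  ds[S_PAS] = (g.painf - s[S_PAS]) / g.tpaS;
  ds[S_PIY] = (g.piinf - s[S_PIY]) / g.tpi;
  ds[S_N]   = (g.ninf - s[S_N]) / g.tn;
  ds[S_Q]   = (g.qinf - s[S_Q]) / g.tq;
  ds[S_R]   = (g.rinf - s[S_R]) / g.tr;
  ds[S_Y]   = (g.yinf - s[S_Y]) / g.ty;
  ds[S_QA]  = (g.qainf - s[S_QA]) / g.tqa;
  ds[S_QI]  = (g.qiinf - s[S_QI]) / g.tqi;

  // --- RyR gating (SR-load-dependent Shannon-type scheme) ---
  // Saturating rate terms use nonnegative concentrations so that transient
  // sub-zero discretization undershoots (possible under very strong
  // hyperpolarizing injections) remain self-correcting instead of feeding
  // singular denominators.
  double casub = s[S_CASUB] > 0.0 ? s[S_CASUB] : 0.0;
  double cajsr = s[S_CAJSR];
  double kcasr = p[P_MAXSR] - (p[P_MAXSR] - p[P_MINSR]) /
                 (1.0 + std::exp(p[P_HSR] * std::log(p[P_EC50SR] / (cajsr > 1e-12 ? cajsr : 1e-12))));
  double kosrca = p[P_KOCA] / kcasr;
  double kisrca = p[P_KICA] * kcasr;
  double rr = s[S_RR], ro = s[S_RO], ri = s[S_RI];
  double rI = 1.0 - rr - ro - ri; // resting-inactivated
  ds[S_RR] = p[P_KIM] * rI - kisrca * casub * rr -
             (kosrca * casub * casub * rr - p[P_KOM] * ro);
  ds[S_RO] = kosrca * casub * casub * rr - p[P_KOM] * ro -
             (kisrca * casub * ro - p[P_KIM] * ri);
  ds[S_RI] = kisrca * casub * ro - p[P_KIM] * ri -
             (p[P_KOM] * ri - kosrca * casub * casub * rI);

  // --- buffering ---
  double cai = s[S_CAI] > 0.0 ? s[S_CAI] : 0.0;
  double dftc  = p[P_KFTC] * cai * (1.0 - s[S_FTC]) - p[P_KBTC] * s[S_FTC];
  double dftmc = p[P_KFTMC] * cai * (1.0 - s[S_FTMC] - s[S_FTMM]) -
                 p[P_KBTMC] * s[S_FTMC];
  double dftmm = p[P_KFTMM] * p[P_MGI] * (1.0 - s[S_FTMC] - s[S_FTMM]) -
                 p[P_KBTMM] * s[S_FTMM];
  double dfcmi = p[P_KFCM] * cai * (1.0 - s[S_FCMI]) - p[P_KBCM] * s[S_FCMI];
  double dfcms = p[P_KFCM] * casub * (1.0 - s[S_FCMS]) - p[P_KBCM] * s[S_FCMS];
  double dfcq  = p[P_KFCQ] * cajsr * (1.0 - s[S_FCQ]) - p[P_KBCQ] * s[S_FCQ];
  ds[S_FTC] = dftc; ds[S_FTMC] = dftmc; ds[S_FTMM] = dftmm;
  ds[S_FCMI] = dfcmi; ds[S_FCMS] = dfcms; ds[S_FCQ] = dfcq;

  // --- Ca fluxes (mM/ms) ---
  double jup  = (p[P_PUP] / 1000.0) * cai / (cai + p[P_KUP]); // P_up given mM/s
  double jtr  = (s[S_CANSR] - cajsr) / p[P_TTR];
  double jrel = p[P_KS] * ro * (cajsr - s[S_CASUB]);
  double jdif = (s[S_CASUB] - s[S_CAI]) / p[P_TDIFCA];

  ds[S_CAI] = (jdif * p[P_VSUB] - jup * p[P_VNSR]) / p[P_VI] -
              (p[P_CMTOT] * dfcmi + p[P_TCTOT] * dftc + p[P_TMCTOT] * dftmc);
  ds[S_CASUB] = jrel * p[P_VJSR] / p[P_VSUB] -
                (ical + icat - 2.0 * incx) / (2.0 * FARADAY * p[P_VSUB]) -
                jdif - p[P_CMTOT] * dfcms + j_lcr;
  ds[S_CANSR] = jup - jtr * p[P_VJSR] / p[P_VNSR];
  ds[S_CAJSR] = jtr - jrel - p[P_CQTOT] * dfcq;
}

// One fixed-step update: forward Euler for Vm, concentrations, RyR states and
// buffers; Rush-Larsen exponential relaxation for the gating variables (their
// tabulated factors 1-exp(-dt/tau) live in g), which keeps gates in [0,1] and
// removes the gating stiffness limit on dt.  f_Ca has a Ca-dependent time
// constant and gets its exponential factor computed directly.
static inline void advance(double* s, const double* ds, const VDep& g,
                           const double* p, double dt) {
  s[S_VM] += dt * ds[S_VM];
  s[S_CAI] += dt * ds[S_CAI];
  s[S_CASUB] += dt * ds[S_CASUB];
  s[S_CANSR] += dt * ds[S_CANSR];
  s[S_CAJSR] += dt * ds[S_CAJSR];
  s[S_RR] += dt * ds[S_RR];
  s[S_RO] += dt * ds[S_RO];
  s[S_RI] += dt * ds[S_RI];
  s[S_FCMI] += dt * ds[S_FCMI];
  s[S_FCMS] += dt * ds[S_FCMS];
  s[S_FTC] += dt * ds[S_FTC];
  s[S_FTMC] += dt * ds[S_FTMC];
  s[S_FTMM] += dt * ds[S_FTMM];
  s[S_FCQ] += dt * ds[S_FCQ];
  s[S_DL] += (g.dLinf - s[S_DL]) * g.rl_dL;
  s[S_FL] += (g.fLinf - s[S_FL]) * g.rl_fL;
  s[S_DT] += (g.dTinf - s[S_DT]) * g.rl_dT;
  s[S_FT] += (g.fTinf - s[S_FT]) * g.rl_fT;
  s[S_PAF] += (g.painf - s[S_PAF]) * g.rl_paF;
  s[S_PAS] += (g.painf - s[S_PAS]) * g.rl_paS;
  s[S_PIY] += (g.piinf - s[S_PIY]) * g.rl_piy;
  s[S_N] += (g.ninf - s[S_N]) * g.rl_n;
  s[S_Q] += (g.qinf - s[S_Q]) * g.rl_q;
  s[S_R] += (g.rinf - s[S_R]) * g.rl_r;
  s[S_Y] += (g.yinf - s[S_Y]) * g.rl_y;
  s[S_QA] += (g.qainf - s[S_QA]) * g.rl_qa;
  s[S_QI] += (g.qiinf - s[S_QI]) * g.rl_qi;
  {
    double casub = s[S_CASUB] > 0.0 ? s[S_CASUB] : 0.0;
    double fcainf = p[P_KMFCA] / (p[P_KMFCA] + casub);
    double tfca = fcainf / p[P_ALPHAFCA];
    s[S_FCA] += (fcainf - s[S_FCA]) * -std::expm1(-dt / tfca);
  }
}

// Positivity-preserving fallback step for the Ca concentrations, used only
// when the plain update would drive a concentration negative (possible during
// extreme-amplitude current injections, where sarcolemmal Ca fluxes become
// stiff).  Each concentration's rate is split into production P and removal
// L*c and updated as c <- (c + dt*P)/(1 + dt*L), which is first-order
// accurate and keeps c >= 0.  Gates, buffers, RyR and V_m advance as usual.
static void advance_pos(double* s, const double* ds, const VDep& g,
                        const double* p, double dt, double i_stim,
                        double j_lcr) {
  double cur[NCUR];
  double dum[NSTATE];
  derivs(s, p, g, i_stim, j_lcr, dum, cur);

  double cai = s[S_CAI] > 0.0 ? s[S_CAI] : 0.0;
  double casub = s[S_CASUB] > 0.0 ? s[S_CASUB] : 0.0;
  double cajsr = s[S_CAJSR] > 0.0 ? s[S_CAJSR] : 0.0;
  double cansr = s[S_CANSR] > 0.0 ? s[S_CANSR] : 0.0;

  double jup = (p[P_PUP] / 1000.0) * cai / (cai + p[P_KUP]);
  double ro = s[S_RO];
  double jsl = -(cur[C_ICAL] + cur[C_ICAT] - 2.0 * cur[C_INCX]) /
               (2.0 * FARADAY * p[P_VSUB]);

  // Ca_sub
  double Ps = p[P_KS] * ro * cajsr * p[P_VJSR] / p[P_VSUB] +
              cai / p[P_TDIFCA] + p[P_CMTOT] * p[P_KBCM] * s[S_FCMS] + j_lcr;
  double Ls = p[P_KS] * ro * p[P_VJSR] / p[P_VSUB] + 1.0 / p[P_TDIFCA] +
              p[P_CMTOT] * p[P_KFCM] * (1.0 - s[S_FCMS]);
  if (jsl >= 0.0) Ps += jsl;
  else if (casub > 1e-12) Ls += -jsl / casub;

  // Ca_i
  double vr = p[P_VSUB] / p[P_VI];
  double Pi = casub / p[P_TDIFCA] * vr +
              p[P_CMTOT] * p[P_KBCM] * s[S_FCMI] +
              p[P_TCTOT] * p[P_KBTC] * s[S_FTC] +
              p[P_TMCTOT] * p[P_KBTMC] * s[S_FTMC];
  double Li = vr / p[P_TDIFCA] +
              (p[P_PUP] / 1000.0) / (cai + p[P_KUP]) * p[P_VNSR] / p[P_VI] +
              p[P_CMTOT] * p[P_KFCM] * (1.0 - s[S_FCMI]) +
              p[P_TCTOT] * p[P_KFTC] * (1.0 - s[S_FTC]) +
              p[P_TMCTOT] * p[P_KFTMC] * (1.0 - s[S_FTMC] - s[S_FTMM]);

  // Ca_jSR
  double Pj = cansr / p[P_TTR] + p[P_KS] * ro * casub +
              p[P_CQTOT] * p[P_KBCQ] * s[S_FCQ];
  double Lj = 1.0 / p[P_TTR] + p[P_KS] * ro +
              p[P_CQTOT] * p[P_KFCQ] * (1.0 - s[S_FCQ]);

  // Ca_nSR
  double vj = p[P_VJSR] / p[P_VNSR];
  double Pn = jup + cajsr / p[P_TTR] * vj;
  double Ln = vj / p[P_TTR];

  // everything except the four concentrations advances as usual
  double keep_i = s[S_CAI], keep_s = s[S_CASUB], keep_j = s[S_CAJSR],
         keep_n = s[S_CANSR];
  advance(s, ds, g, p, dt);
  (void)keep_i; (void)keep_s; (void)keep_j; (void)keep_n;
  s[S_CAI] = (cai + dt * Pi) / (1.0 + dt * Li);
  s[S_CASUB] = (casub + dt * Ps) / (1.0 + dt * Ls);
  s[S_CAJSR] = (cajsr + dt * Pj) / (1.0 + dt * Lj);
  s[S_CANSR] = (cansr + dt * Pn) / (1.0 + dt * Ln);
}

static inline bool ca_ok(const double* s) {
  return s[S_CAI] >= 0.0 && s[S_CASUB] >= 0.0 && s[S_CAJSR] >= 0.0 &&
         s[S_CANSR] >= 0.0;
}

// total Ca content (free + buffered, volume weighted; attomol-scale, pL*mM)
static double total_ca(const double* s, const double* p) {
  double cyt = p[P_VI] * (s[S_CAI] + p[P_CMTOT] * s[S_FCMI] +
                          p[P_TCTOT] * s[S_FTC] + p[P_TMCTOT] * s[S_FTMC]);
  double sub = p[P_VSUB] * (s[S_CASUB] + p[P_CMTOT] * s[S_FCMS]);
  double nsr = p[P_VNSR] * s[S_CANSR];
  double jsr = p[P_VJSR] * (s[S_CAJSR] + p[P_CQTOT] * s[S_FCQ]);
  return cyt + sub + nsr + jsr;
}

// ------------------------------------------------------------- stimulus
// Segment matrix columns: kind (0 none, 1 sine, 2 noise), t0, t1 (ms),
// amplitude (pA), freq (Hz), hold (ms), offset into noise-value vector.
struct Stim {
  const double* seg; int nseg;
  const double* vals;
  int cur;
  Stim(const double* s, int n, const double* v) : seg(s), nseg(n), vals(v), cur(0) {}
  inline double at(double t) {
    while (cur < nseg && t >= seg[cur + 2 * nseg]) cur++; // t >= t1 -> next
    if (cur >= nseg) return 0.0;
    double t0 = seg[cur + 1 * nseg];
    if (t < t0) return 0.0;
    int kind = (int)seg[cur + 0 * nseg];
    double a = seg[cur + 3 * nseg];
    if (kind == 1) {
      double f = seg[cur + 4 * nseg]; // Hz; t in ms
      return a * std::sin(2.0 * M_PI * f * (t - t0) / 1000.0);
    } else if (kind == 2) {
      double hold = seg[cur + 5 * nseg];
      int off = (int)seg[cur + 6 * nseg];
      int nv = (int)((seg[cur + 2 * nseg] - t0) / hold + 0.5);
      int idx = (int)((t - t0) / hold);
      if (idx >= nv) idx = nv - 1;
      return vals[off + idx];
    }
    return 0.0;
  }
};

// ------------------------------------------------------------ R interface

// [[Rcpp::export]]
CharacterVector cm_param_names() {
  CharacterVector out(NPAR);
  for (int i = 0; i < NPAR; i++) out[i] = PAR_NAMES[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector cm_state_names() {
  CharacterVector out(NSTATE);
  for (int i = 0; i < NSTATE; i++) out[i] = STATE_NAMES[i];
  return out;
}

// [[Rcpp::export]]
List cm_derivs(NumericVector state, NumericVector params, double i_inject) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (params.size() != NPAR) stop("params must have %d elements", NPAR);
  for (int i = 0; i < NSTATE; i++)
    if (!std::isfinite(state[i])) stop("non-finite state variable '%s'", STATE_NAMES[i]);
  VDep g;
  vdep_exact(state[S_VM], params.begin(), &g);
  NumericVector ds(NSTATE), cur(NCUR);
  derivs(state.begin(), params.begin(), g, i_inject, 0.0,
         ds.begin(), cur.begin());
  ds.attr("names") = cm_state_names();
  cur.attr("names") = CharacterVector::create(
    "I_CaL", "I_CaT", "I_Kr", "I_Ks", "I_to", "I_sus", "I_f", "I_st",
    "I_bNa", "I_NaK", "I_NCX", "I_KACh", "I_tot");
  return List::create(_["dstate"] = ds, _["currents"] = cur);
}

// Fixed-step explicit integration of a single cell.
// lcr_times: sorted onset times (ms) of stochastic unitary Ca release events,
// each adding lcr_flux (mM/ms) into Ca_sub for lcr_dur (ms).
// [[Rcpp::export]]
List cm_simulate(NumericVector state0, NumericVector params,
                 double dt, double duration_ms, int record_every,
                 NumericMatrix seg, NumericVector noisevals,
                 NumericVector lcr_times, double lcr_flux, double lcr_dur,
                 bool record_states = false) {
  if (state0.size() != NSTATE) stop("state0 must have %d elements", NSTATE);
  if (params.size() != NPAR) stop("params must have %d elements", NPAR);
  if (dt <= 0) stop("dt must be positive");

  long nstep = (long)std::floor(duration_ms / dt + 0.5);
  long nrec = nstep / record_every + 1;

  VTab tab;
  tab.build(params.begin(), dt);

  std::vector<double> s(state0.begin(), state0.end());
  std::vector<double> ds(NSTATE), sold(NSTATE);
  double cur[NCUR];
  VDep g;

  NumericVector rt(nrec), rvm(nrec), rcai(nrec), rcasub(nrec), rcansr(nrec),
      rcajsr(nrec), rical(nrec), rincx(nrec), rikach(nrec), ristim(nrec),
      rcatot(nrec);
  NumericMatrix rstates = record_states ? NumericMatrix(nrec, NSTATE)
                                        : NumericMatrix(1, 1);

  Stim stim(seg.begin(), seg.nrow(), noisevals.begin());
  int nlcr = lcr_times.size();
  int lcr_lo = 0;

  long irec = 0;
  for (long k = 0; k <= nstep; k++) {
    double t = k * dt;
    double istim = stim.at(t);

    // stochastic LCR flux: sum of active unitary events
    double jl = 0.0;
    if (nlcr > 0) {
      while (lcr_lo < nlcr && lcr_times[lcr_lo] + lcr_dur <= t) lcr_lo++;
      for (int e = lcr_lo; e < nlcr && lcr_times[e] <= t; e++) jl += lcr_flux;
    }

    tab.eval(s[S_VM], &g);
    bool rec = (k % record_every == 0);
    derivs(&s[0], params.begin(), g, istim, jl, &ds[0], rec ? cur : (double*)0);

    if (rec) {
      rt[irec] = t / 1000.0;
      rvm[irec] = s[S_VM];
      rcai[irec] = s[S_CAI];
      rcasub[irec] = s[S_CASUB];
      rcansr[irec] = s[S_CANSR];
      rcajsr[irec] = s[S_CAJSR];
      rical[irec] = cur[C_ICAL];
      rincx[irec] = cur[C_INCX];
      rikach[irec] = cur[C_IKACH];
      ristim[irec] = istim;
      rcatot[irec] = total_ca(&s[0], params.begin());
      if (record_states)
        for (int j = 0; j < NSTATE; j++) rstates(irec, j) = s[j];
      irec++;
    }
    if (k == nstep) break;

    std::copy(s.begin(), s.end(), sold.begin());
    advance(&s[0], &ds[0], g, params.begin(), dt);
    if (!ca_ok(&s[0])) {
      std::copy(sold.begin(), sold.end(), s.begin());
      advance_pos(&s[0], &ds[0], g, params.begin(), dt, istim, jl);
    }

    if (!(s[S_VM] > -620.0 && s[S_VM] < 450.0))
      stop("numerical blow-up at t = %.4f s (V_m non-finite or out of range); reduce dt",
           t / 1000.0);
  }

  List out = List::create(
      _["time"] = rt, _["V_m"] = rvm, _["Ca_i"] = rcai, _["Ca_sub"] = rcasub,
      _["Ca_nSR"] = rcansr, _["Ca_jSR"] = rcajsr, _["I_CaL"] = rical,
      _["I_NCX"] = rincx, _["I_KACh"] = rikach, _["i_stim"] = ristim,
      _["ca_total"] = rcatot,
      _["final_state"] = NumericVector(s.begin(), s.end()));
  if (record_states) out["states"] = rstates;
  return out;
}

// 2-D lattice of electrically coupled cells.  All cells share `params`
// except P_up, given per cell (mM/s).  Nearest-neighbour (von Neumann)
// coupling with no-flux boundaries: I_gap,i = g_gap * sum_j (V_i - V_j).
// noise: ncell x nhold matrix of per-cell sample-and-hold current values
// (pA, hold interval `hold` ms); pass a 1x1 matrix with NA to disable.
// [[Rcpp::export]]
List cm_simulate_tissue(NumericVector state0, NumericVector params,
                        NumericVector pup_cells, int nx, int ny, double g_gap,
                        NumericMatrix noise, double hold,
                        double dt, double duration_ms, int record_every) {
  if (state0.size() != NSTATE) stop("state0 must have %d elements", NSTATE);
  int ncell = nx * ny;
  if (pup_cells.size() != ncell) stop("pup_cells must have nx*ny elements");
  bool has_noise = !(noise.nrow() == 1 && noise.ncol() == 1 &&
                     NumericVector::is_na(noise(0, 0)));
  if (has_noise && noise.nrow() != ncell)
    stop("noise matrix must have one row per cell");

  long nstep = (long)std::floor(duration_ms / dt + 0.5);
  long nrec = nstep / record_every + 1;

  VTab tab;
  tab.build(params.begin(), dt);

  std::vector<double> pc(params.begin(), params.end());
  std::vector<double> S((size_t)ncell * NSTATE), D((size_t)ncell * NSTATE);
  for (int c = 0; c < ncell; c++)
    for (int j = 0; j < NSTATE; j++) S[(size_t)c * NSTATE + j] = state0[j];

  NumericMatrix rvm(nrec, ncell);
  NumericVector rt(nrec), rmean(nrec);
  std::vector<VDep> gs(ncell);
  std::vector<double> eff(ncell), sold(NSTATE);
  int nhold = has_noise ? noise.ncol() : 0;

  long irec = 0;
  for (long k = 0; k <= nstep; k++) {
    double t = k * dt;
    int ih = has_noise ? (int)(t / hold) : 0;
    if (has_noise && ih >= nhold) ih = nhold - 1;

    bool rec = (k % record_every == 0);
    if (rec) {
      double mv = 0.0;
      for (int c = 0; c < ncell; c++) {
        rvm(irec, c) = S[(size_t)c * NSTATE + S_VM];
        mv += rvm(irec, c);
      }
      rt[irec] = t / 1000.0;
      rmean[irec] = mv / ncell;
      irec++;
    }
    if (k == nstep) break;

    for (int c = 0; c < ncell; c++) {
      double* s = &S[(size_t)c * NSTATE];
      double istim = has_noise ? noise(c, ih) : 0.0;
      // gap-junction coupling (no-flux boundaries)
      int cx = c % nx, cy = c / nx;
      double vsum = 0.0; int nn = 0;
      if (cx > 0)      { vsum += S[(size_t)(c - 1) * NSTATE + S_VM]; nn++; }
      if (cx < nx - 1) { vsum += S[(size_t)(c + 1) * NSTATE + S_VM]; nn++; }
      if (cy > 0)      { vsum += S[(size_t)(c - nx) * NSTATE + S_VM]; nn++; }
      if (cy < ny - 1) { vsum += S[(size_t)(c + nx) * NSTATE + S_VM]; nn++; }
      double igap = g_gap * (nn * s[S_VM] - vsum); // pA
      pc[P_PUP] = pup_cells[c];
      eff[c] = istim - igap;
      tab.eval(s[S_VM], &gs[c]);
      derivs(s, &pc[0], gs[c], eff[c], 0.0, &D[(size_t)c * NSTATE], (double*)0);
    }
    for (int c = 0; c < ncell; c++) {
      pc[P_PUP] = pup_cells[c];
      double* sc = &S[(size_t)c * NSTATE];
      std::copy(sc, sc + NSTATE, sold.begin());
      advance(sc, &D[(size_t)c * NSTATE], gs[c], &pc[0], dt);
      if (!ca_ok(sc)) {
        std::copy(sold.begin(), sold.end(), sc);
        advance_pos(sc, &D[(size_t)c * NSTATE], gs[c], &pc[0], dt, eff[c], 0.0);
      }
      double v = S[(size_t)c * NSTATE + S_VM];
      if (!(v > -620.0 && v < 450.0))
        stop("numerical blow-up in cell %d at t = %.4f s; reduce dt", c + 1, t / 1000.0);
    }
  }

  return List::create(_["time"] = rt, _["V_m_cells"] = rvm,
                      _["V_m_mean"] = rmean);
}
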