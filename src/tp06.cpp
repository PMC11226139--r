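// ten Tusscher-Panfilov 2006 (TP06) human ventricular membrane kinetics with
// a wild-type / G406R-mutant (Timothy syndrome) ICaL mixture:
//   ICaL = (1 - rho) * ICaL_WT + rho * ICaL_TS
// The two variants carry independent activation (d) and voltage-inactivation
// (f) gates with variant-specific steady-state curves but TP06 time
// constants; f2 and fCass are shared.  IKs conductance is scaled by a
// layer-dependent factor (transmural heterogeneity).
//
// State layout (21 variables per node):
//  0 V    [mV]      6 m     12 r        18 f2
//  1 Ki   [mM]      7 h     13 s        19 fCass
//  2 Nai  [mM]      8 j     14 d_wt     20 Rbar (RyR adaptation)
//  3 Cai  [mM]      9 Xr1   15 f_wt
//  4 CaSS [mM]     10 Xr2   16 d_ts
//  5 CaSR [mM]     11 Xs    17 f_ts
//
// Time stepping mirrors the operator-splitting ODE stage: gates advanced by
// Rush-Larsen exponential updates with V frozen at V^n, concentrations by a
// forward step using the updated gates, and the ionic current for the V
// update evaluated at (V^n, w^{n+1}, c^{n+1}).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSTATE = 21;

// physical constants
static const double RGAS = 8314.472;   // mJ/(mol K)
static const double FRDY = 96485.3415; // C/mol
static const double TEMP = 310.0;      // K
static const double RTONF = RGAS * TEMP / FRDY;

// extracellular concentrations [mM]
static const double Ko = 5.4, Cao = 2.0, Nao = 140.0;

// cell geometry / capacitance (TP06 reference values)
static const double CAPACITANCE = 0.185; // uF
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468; // 1e3 um^3

// maximal conductances / fluxes (TP06 reference values)
static const double Gna = 14.838, Gk1 = 5.405, Gkr = 0.153;
static const double Gbna = 0.00029, Gbca = 0.000592;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double gCaL = 0.00003980;
static const double pKNa = 0.03, knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1;
static const double ncagamma = 0.35, nca_alpha = 2.5;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
                    Bufss = 0.4, Kbufss = 0.00025;

// Cell parameter bundle. gate params: activation (va05, sa) and
// voltage-inactivation (vina05, sina) midpoints/slopes per ICaL variant.
struct CellP {
  double rho;
  double va05_wt, sa_wt, vina05_wt, sina_wt;
  double va05_ts, sa_ts, vina05_ts, sina_ts;
  double iks_factor;
  int cell_type; // 0 = epicardial, 1 = endocardial, 2 = midmyocardial (M)
  double ts_floor; // non-inactivating fraction of mutant channels (0 = none)
  double Gks, Gto;
};

static CellP unpack_params(const NumericVector &p) {
  CellP c;
  c.rho = p[0];
  c.va05_wt = p[1]; c.sa_wt = p[2]; c.vina05_wt = p[3]; c.sina_wt = p[4];
  c.va05_ts = p[5]; c.sa_ts = p[6]; c.vina05_ts = p[7]; c.sina_ts = p[8];
  c.iks_factor = p[9];
  c.cell_type = (int)p[10];
  c.ts_floor = p.size() > 11 ? p[11] : 0.0;
  switch (c.cell_type) {
  case 1: c.Gks = 0.392; c.Gto = 0.073; break;  // endo
  case 2: c.Gks = 0.098; c.Gto = 0.294; break;  // M
  default: c.Gks = 0.392; c.Gto = 0.294; break; // epi
  }
  return c;
}

static inline double sigmoid_up(double V, double v05, double s) {
  return 1.0 / (1.0 + std::exp((v05 - V) / s));
}
static inline double sigmoid_down(double V, double v05, double s) {
  return 1.0 / (1.0 + std::exp((V - v05) / s));
}

// voltage-dependent rates evaluated once per node per step
struct Rates {
  double m_inf, tau_m, h_inf, tau_h, j_inf, tau_j;
  double xr1_inf, tau_xr1, xr2_inf, tau_xr2, xs_inf, tau_xs;
  double r_inf, tau_r, s_inf, tau_s;
  double d_inf_wt, d_inf_ts, tau_d, f_inf_wt, f_inf_ts, tau_f;
  double f2_inf, tau_f2;
};

static void compute_rates(double V, const CellP &p, Rates &rt) {
  // fast sodium current gates
  double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  rt.tau_m = am * bm;
  rt.m_inf = 1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
                    (1.0 + std::exp((-56.86 - V) / 9.03)));
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  rt.tau_h = 1.0 / (ah + bh);
  rt.h_inf = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                    (1.0 + std::exp((V + 71.55) / 7.43)));
  rt.tau_j = 1.0 / (aj + bj);
  rt.j_inf = rt.h_inf;

  // rapid delayed rectifier gates
  double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  rt.tau_xr1 = axr1 * bxr1;
  rt.xr1_inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  rt.tau_xr2 = axr2 * bxr2;
  rt.xr2_inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));

  // slow delayed rectifier gate
  double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  rt.tau_xs = axs * bxs + 80.0;
  rt.xs_inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));

  // transient outward gates (s kinetics differ for endocardial cells)
  rt.r_inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  rt.tau_r = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  if (p.cell_type == 1) {
    rt.s_inf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    rt.tau_s = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {
    rt.s_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    rt.tau_s = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
               5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }

  // L-type calcium gates: variant-specific steady states, TP06 time constants
  double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  rt.tau_d = ad * bd + cd;
  rt.d_inf_wt = sigmoid_up(V, p.va05_wt, p.sa_wt);
  rt.d_inf_ts = sigmoid_up(V, p.va05_ts, p.sa_ts);
  rt.tau_f = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
             200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
             180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  rt.f_inf_wt = sigmoid_down(V, p.vina05_wt, p.sina_wt);
  rt.f_inf_ts = (1.0 - p.ts_floor) * sigmoid_down(V, p.vina05_ts, p.sina_ts) +
                p.ts_floor;
  rt.f2_inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  rt.tau_f2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
              31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
              80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
}

// GHK-type ICaL driving term shared by both variants (per unit gate product)
static inline double ical_drive(double V, double CaSS) {
  double z = 2.0 * (V - 15.0) / RTONF;
  if (std::fabs(z) < 1e-7) z = (z >= 0 ? 1e-7 : -1e-7);
  double ez = std::exp(z);
  return gCaL * 4.0 * (V - 15.0) * FRDY / RTONF *
         (0.25 * CaSS * ez - Cao) / (ez - 1.0);
}

struct Currents {
  double INa, ICaL, ICaL_wt, ICaL_ts, Ito, IKr, IKs, IK1, INaCa, INaK,
      IpCa, IpK, IbNa, IbCa;
  double Iion; // total (pA/pF), excluding applied current
};

// currents at the given (V, gates, concentrations)
static void compute_currents(const double *s, const CellP &p, Currents &cu) {
  double V = s[0], Ki = s[1], Nai = s[2], Cai = s[3], CaSS = s[4];
  double Ek = RTONF * std::log(Ko / Ki);
  double Ena = RTONF * std::log(Nao / Nai);
  double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  cu.INa = Gna * s[6] * s[6] * s[6] * s[7] * s[8] * (V - Ena);

  double drive = ical_drive(V, CaSS);
  cu.ICaL_wt = drive * s[14] * s[15] * s[18] * s[19];
  cu.ICaL_ts = drive * s[16] * s[17] * s[18] * s[19];
  cu.ICaL = (1.0 - p.rho) * cu.ICaL_wt + p.rho * cu.ICaL_ts;

  cu.Ito = p.Gto * s[12] * s[13] * (V - Ek);
  cu.IKr = Gkr * std::sqrt(Ko / 5.4) * s[9] * s[10] * (V - Ek);
  cu.IKs = p.Gks * p.iks_factor * s[11] * s[11] * (V - Eks);

  double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                std::exp(0.1 * (V - Ek - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - Ek)));
  cu.IK1 = Gk1 * Ak1 / (Ak1 + Bk1) * (V - Ek);

  cu.INaCa = knaca * (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
             (1.0 / (KmCa + Cao)) *
             (1.0 / (1.0 + ksat * std::exp((ncagamma - 1.0) * V / RTONF))) *
             (std::exp(ncagamma * V / RTONF) * Nai * Nai * Nai * Cao -
              std::exp((ncagamma - 1.0) * V / RTONF) * Nao * Nao * Nao * Cai *
                  nca_alpha);
  cu.INaK = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
            (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
             0.0353 * std::exp(-V / RTONF));
  cu.IpCa = GpCa * Cai / (KpCa + Cai);
  cu.IpK = GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  cu.IbNa = Gbna * (V - Ena);
  cu.IbCa = Gbca * (V - Eca);

  cu.Iion = cu.INa + cu.ICaL + cu.Ito + cu.IKr + cu.IKs + cu.IK1 + cu.INaCa +
            cu.INaK + cu.IpCa + cu.IpK + cu.IbNa + cu.IbCa;
}

// ODE stage of the operator splitting: advance gates (Rush-Larsen, V frozen)
// and concentrations in place, then return the ionic current evaluated at
// (V^n, w^{n+1}, c^{n+1}) for the voltage update.  istim in pA/pF enters the
// Ki bookkeeping as in the TP06 reference code (positive = depolarizing).
static double tp06_ode_step(double *s, const CellP &p, double tau,
                            double istim) {
  double V = s[0];
  Rates rt;
  compute_rates(V, p, rt);

  // Rush-Larsen exponential gate updates
  s[6] = rt.m_inf - (rt.m_inf - s[6]) * std::exp(-tau / rt.tau_m);
  s[7] = rt.h_inf - (rt.h_inf - s[7]) * std::exp(-tau / rt.tau_h);
  s[8] = rt.j_inf - (rt.j_inf - s[8]) * std::exp(-tau / rt.tau_j);
  s[9] = rt.xr1_inf - (rt.xr1_inf - s[9]) * std::exp(-tau / rt.tau_xr1);
  s[10] = rt.xr2_inf - (rt.xr2_inf - s[10]) * std::exp(-tau / rt.tau_xr2);
  s[11] = rt.xs_inf - (rt.xs_inf - s[11]) * std::exp(-tau / rt.tau_xs);
  s[12] = rt.r_inf - (rt.r_inf - s[12]) * std::exp(-tau / rt.tau_r);
  s[13] = rt.s_inf - (rt.s_inf - s[13]) * std::exp(-tau / rt.tau_s);
  s[14] = rt.d_inf_wt - (rt.d_inf_wt - s[14]) * std::exp(-tau / rt.tau_d);
  s[15] = rt.f_inf_wt - (rt.f_inf_wt - s[15]) * std::exp(-tau / rt.tau_f);
  s[16] = rt.d_inf_ts - (rt.d_inf_ts - s[16]) * std::exp(-tau / rt.tau_d);
  s[17] = rt.f_inf_ts - (rt.f_inf_ts - s[17]) * std::exp(-tau / rt.tau_f);
  s[18] = rt.f2_inf - (rt.f2_inf - s[18]) * std::exp(-tau / rt.tau_f2);
  double fcass_inf = 0.6 / (1.0 + (s[4] / 0.05) * (s[4] / 0.05)) + 0.4;
  double tau_fcass = 80.0 / (1.0 + (s[4] / 0.05) * (s[4] / 0.05)) + 2.0;
  s[19] = fcass_inf - (fcass_inf - s[19]) * std::exp(-tau / tau_fcass);

  // RyR adaptation variable (linear in Rbar for frozen CaSS)
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / s[5]) * (EC / s[5]));
  double k2 = k2p * kCaSR;
  double rr_rate = k4 + k2 * s[4];
  double rr_inf = k4 / rr_rate;
  s[20] = rr_inf - (rr_inf - s[20]) * std::exp(-tau * rr_rate);

  // currents with updated gates, pre-update concentrations
  Currents cu;
  compute_currents(s, p, cu);

  // calcium subsystem fluxes
  double k1 = k1p / kCaSR;
  double O = k1 * s[4] * s[4] * s[20] / (k3 + k1 * s[4] * s[4]);
  double Irel = Vrel * O * (s[5] - s[4]);
  double Ileak = Vleak * (s[5] - s[4]);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (s[3] * s[3]));
  double Ixfer = Vxfer * (s[4] - s[3]);

  // SR calcium with instantaneous-buffer correction (quadratic solve)
  double CaCSQN = Bufsr * s[5] / (s[5] + Kbufsr);
  double dCaSR = tau * (Iup - Irel - Ileak);
  double bjsr = Bufsr - CaCSQN - dCaSR - s[5] + Kbufsr;
  double cjsr = Kbufsr * (CaCSQN + dCaSR + s[5]);
  s[5] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  // subspace calcium
  double CaSSBuf = Bufss * s[4] / (s[4] + Kbufss);
  double dCaSS = tau * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
                        (-cu.ICaL / (2.0 * Vss * FRDY) * CAPACITANCE));
  double bcss = Bufss - CaSSBuf - dCaSS - s[4] + Kbufss;
  double ccss = Kbufss * (CaSSBuf + dCaSS + s[4]);
  s[4] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  // bulk cytosolic calcium
  double CaBuf = Bufc * s[3] / (s[3] + Kbufc);
  double dCai = tau * (-(cu.IbCa + cu.IpCa - 2.0 * cu.INaCa) /
                           (2.0 * Vc * FRDY) * CAPACITANCE -
                       (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  double bc = Bufc - CaBuf - dCai - s[3] + Kbufc;
  double cc = Kbufc * (CaBuf + dCai + s[3]);
  s[3] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  // sodium and potassium
  s[2] += -tau * (cu.INa + cu.IbNa + 3.0 * cu.INaK + 3.0 * cu.INaCa) /
          (Vc * FRDY) * CAPACITANCE;
  s[1] += -tau * (cu.IK1 + cu.Ito + cu.IKr + cu.IKs - 2.0 * cu.INaK + cu.IpK -
                  istim) /
          (Vc * FRDY) * CAPACITANCE;

  // ionic current for the V update, re-evaluated at c^{n+1}
  Currents cu2;
  compute_currents(s, p, cu2);
  return cu2.Iion;
}

static NumericVector state_template() {
  NumericVector s(NSTATE);
  s[0] = -86.2;  // V
  s[1] = 138.3;  // Ki
  s[2] = 7.67;   // Nai
  s[3] = 0.00007; // Cai
  s[4] = 0.00007; // CaSS
  s[5] = 1.3;    // CaSR
  s[6] = 0.0;    // m
  s[7] = 0.75;   // h
  s[8] = 0.75;   // j
  s[9] = 0.0;    // Xr1
  s[10] = 1.0;   // Xr2
  s[11] = 0.0;   // Xs
  s[12] = 0.0;   // r
  s[13] = 1.0;   // s
  s[14] = 0.0;   // d_wt
  s[15] = 1.0;   // f_wt
  s[16] = 0.0;   // d_ts
  s[17] = 1.0;   // f_ts
  s[18] = 1.0;   // f2
  s[19] = 1.0;   // fCass
  s[20] = 1.0;   // Rbar
  CharacterVector nm = CharacterVector::create(
      "V", "Ki", "Nai", "Cai", "CaSS", "CaSR", "m", "h", "j", "Xr1", "Xr2",
      "Xs", "r", "s", "d_wt", "f_wt", "d_ts", "f_ts", "f2", "fCass", "Rbar");
  s.attr("names") = nm;
  return s;
}

static void check_finite(const double *s, int n, double t) {
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(s[i]))
      stop("non-finite state variable at t = %f ms (index %d)", t, i + 1);
}

// [[Rcpp::export(name = ".tp06_initial_state_cpp")]]
NumericVector tp06_initial_state_cpp() { return state_template(); }

// [[Rcpp::export(name = ".tp06_currents_cpp")]]
NumericVector tp06_currents_cpp(NumericVector state, NumericVector params) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  CellP p = unpack_params(params);
  Currents cu;
  compute_currents(REAL(state), p, cu);
  NumericVector out = NumericVector::create(
      _["INa"] = cu.INa, _["ICaL"] = cu.ICaL, _["ICaL_wt"] = cu.ICaL_wt,
      _["ICaL_ts"] = cu.ICaL_ts, _["Ito"] = cu.Ito, _["IKr"] = cu.IKr,
      _["IKs"] = cu.IKs, _["IK1"] = cu.IK1, _["INaCa"] = cu.INaCa,
      _["INaK"] = cu.INaK, _["IpCa"] = cu.IpCa, _["IpK"] = cu.IpK,
      _["IbNa"] = cu.IbNa, _["IbCa"] = cu.IbCa, _["Iion"] = cu.Iion);
  return out;
}

// Full time derivative of the state (true ODE right-hand side; gates as
// (w_inf - w)/tau_w).  Used for diagnostics and equilibrium tests.
// [[Rcpp::export(name = ".tp06_rhs_cpp")]]
NumericVector tp06_rhs_cpp(NumericVector state, NumericVector params,
                           double i_app) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  const double *s = REAL(state);
  check_finite(s, NSTATE, NA_REAL);
  CellP p = unpack_params(params);
  Rates rt;
  compute_rates(s[0], p, rt);
  Currents cu;
  compute_currents(s, p, cu);

  NumericVector d(NSTATE);
  d[0] = -cu.Iion + i_app;
  d[6] = (rt.m_inf - s[6]) / rt.tau_m;
  d[7] = (rt.h_inf - s[7]) / rt.tau_h;
  d[8] = (rt.j_inf - s[8]) / rt.tau_j;
  d[9] = (rt.xr1_inf - s[9]) / rt.tau_xr1;
  d[10] = (rt.xr2_inf - s[10]) / rt.tau_xr2;
  d[11] = (rt.xs_inf - s[11]) / rt.tau_xs;
  d[12] = (rt.r_inf - s[12]) / rt.tau_r;
  d[13] = (rt.s_inf - s[13]) / rt.tau_s;
  d[14] = (rt.d_inf_wt - s[14]) / rt.tau_d;
  d[15] = (rt.f_inf_wt - s[15]) / rt.tau_f;
  d[16] = (rt.d_inf_ts - s[16]) / rt.tau_d;
  d[17] = (rt.f_inf_ts - s[17]) / rt.tau_f;
  d[18] = (rt.f2_inf - s[18]) / rt.tau_f2;
  double fcass_inf = 0.6 / (1.0 + (s[4] / 0.05) * (s[4] / 0.05)) + 0.4;
  double tau_fcass = 80.0 / (1.0 + (s[4] / 0.05) * (s[4] / 0.05)) + 2.0;
  d[19] = (fcass_inf - s[19]) / tau_fcass;

  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / s[5]) * (EC / s[5]));
  double k1 = k1p / kCaSR, k2 = k2p * kCaSR;
  d[20] = k4 * (1.0 - s[20]) - k2 * s[4] * s[20];
  double O = k1 * s[4] * s[4] * s[20] / (k3 + k1 * s[4] * s[4]);
  double Irel = Vrel * O * (s[5] - s[4]);
  double Ileak = Vleak * (s[5] - s[4]);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (s[3] * s[3]));
  double Ixfer = Vxfer * (s[4] - s[3]);

  double bufsr_fac = 1.0 / (1.0 + Bufsr * Kbufsr / ((s[5] + Kbufsr) * (s[5] + Kbufsr)));
  d[5] = bufsr_fac * (Iup - Irel - Ileak);
  double bufss_fac = 1.0 / (1.0 + Bufss * Kbufss / ((s[4] + Kbufss) * (s[4] + Kbufss)));
  d[4] = bufss_fac * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                      cu.ICaL / (2.0 * Vss * FRDY) * CAPACITANCE);
  double bufc_fac = 1.0 / (1.0 + Bufc * Kbufc / ((s[3] + Kbufc) * (s[3] + Kbufc)));
  d[3] = bufc_fac * (-(cu.IbCa + cu.IpCa - 2.0 * cu.INaCa) /
                         (2.0 * Vc * FRDY) * CAPACITANCE -
                     (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  d[2] = -(cu.INa + cu.IbNa + 3.0 * cu.INaK + 3.0 * cu.INaCa) /
         (Vc * FRDY) * CAPACITANCE;
  d[1] = -(cu.IK1 + cu.Ito + cu.IKr + cu.IKs - 2.0 * cu.INaK + cu.IpK -
           i_app) /
         (Vc * FRDY) * CAPACITANCE;
  d.attr("names") = state_template().attr("names");
  return d;
}

static inline double stim_at(double t, const NumericVector &t0,
                             const NumericVector &dur,
                             const NumericVector &amp) {
  double v = 0.0;
  for (int k = 0; k < t0.size(); ++k)
    if (t >= t0[k] && t < t0[k] + dur[k]) v += amp[k];
  return v;
}

// Space-clamped (0D) paced run.  Records the state every record_dt ms.
// [[Rcpp::export(name = ".cell_run_cpp")]]
List cell_run_cpp(NumericVector state0, NumericVector params, double tau,
                  double t_end, NumericVector stim_t0, NumericVector stim_dur,
                  NumericVector stim_amp, double record_dt) {
  CellP p = unpack_params(params);
  std::vector<double> s(state0.begin(), state0.end());
  if ((int)s.size() != NSTATE) stop("state must have %d entries", NSTATE);
  int nstep = (int)std::round(t_end / tau);
  int every = std::max(1, (int)std::round(record_dt / tau));
  int nrec = nstep / every + 1;
  NumericMatrix rec(nrec, NSTATE);
  NumericVector tvec(nrec);
  int ir = 0;
  for (int q = 0; q < NSTATE; ++q) rec(0, q) = s[q];
  tvec[0] = 0.0;
  ir = 1;
  for (int n = 0; n < nstep; ++n) {
    double t = n * tau;
    double istim = stim_at(t, stim_t0, stim_dur, stim_amp);
    double iion = tp06_ode_step(s.data(), p, tau, istim);
    s[0] += tau * (-iion + istim);
    if (!std::isfinite(s[0]))
      stop("non-finite membrane potential at t = %f ms", t);
    for (int q = 6; q < 20; ++q) {
      if (s[q] < 0.0 || s[q] > 1.0)
        stop("gating variable %d left [0,1] at t = %f ms", q + 1, t);
    }
    if ((n + 1) % every == 0 && ir < nrec) {
      for (int q = 0; q < NSTATE; ++q) rec(ir, q) = s[q];
      tvec[ir] = (n + 1) * tau;
      ++ir;
    }
  }
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = state_template().attr("names");
  colnames(rec) = as<CharacterVector>(state_template().attr("names"));
  return List::create(_["time"] = tvec, _["states"] = rec,
                      _["final_state"] = fin);
}

// Advance all nodes of a tissue/cable by one ODE stage (V frozen); states is
// a NSTATE x n matrix modified in place; returns i_ion per node (pA/pF).
// [[Rcpp::export(name = ".cells_step_cpp")]]
NumericVector cells_step_cpp(NumericMatrix states, NumericVector gate_params,
                             NumericVector rho, NumericVector iks_factor,
                             int cell_type, double tau, NumericVector istim) {
  int n = states.ncol();
  if (states.nrow() != NSTATE) stop("states must be %d x n", NSTATE);
  NumericVector iion(n);
  NumericVector pv(12);
  for (int k = 0; k < 8; ++k) pv[k + 1] = gate_params[k];
  pv[10] = cell_type;
  pv[11] = gate_params.size() > 8 ? gate_params[8] : 0.0;
  for (int i = 0; i < n; ++i) {
    pv[0] = rho.size() == 1 ? rho[0] : rho[i];
    pv[9] = iks_factor.size() == 1 ? iks_factor[0] : iks_factor[i];
    CellP p = unpack_params(pv);
    double *s = &states(0, i);
    double st = istim.size() == 1 ? istim[0] : istim[i];
    iion[i] = tp06_ode_step(s, p, tau, st);
  }
  return iion;
}

// Paced 1D cable (monodomain): semi-implicit splitting with a tridiagonal
// (Thomas) solve for the diffusion step.  deff = sigma / c_m in cm^2/ms.
// stim_nodes are 0-based indices of the stimulated footprint.
// [[Rcpp::export(name = ".cable_run_cpp")]]
List cable_run_cpp(NumericMatrix states0, NumericVector gate_params,
                   NumericVector rho, NumericVector iks_factor, int cell_type,
                   double deff, double h, double tau, double t_end,
                   IntegerVector stim_nodes, NumericVector stim_t0,
                   NumericVector stim_dur, NumericVector stim_amp,
                   IntegerVector probe_nodes, double record_dt,
                   double event_thresh, double event_slope) {
  int n = states0.ncol();
  if (states0.nrow() != NSTATE) stop("states must be %d x n", NSTATE);
  NumericMatrix states = clone(states0);
  int nstep = (int)std::round(t_end / tau);
  int every = std::max(1, (int)std::round(record_dt / tau));
  int nrec = nstep / every + 1;
  int np = probe_nodes.size();
  NumericMatrix traces(nrec, np);
  NumericVector tvec(nrec);

  double alpha = deff * tau / (h * h);
  // tridiagonal system rows: -alpha, 1+2alpha, -alpha with mirrored Neumann
  std::vector<double> a(n, -alpha), b(n, 1.0 + 2.0 * alpha), c(n, -alpha);
  c[0] = -2.0 * alpha;
  a[n - 1] = -2.0 * alpha;
  // Thomas forward sweep coefficients (constant matrix)
  std::vector<double> cp(n), v(n), rhs(n), istim(n, 0.0);
  cp[0] = c[0] / b[0];
  std::vector<double> denom(n);
  denom[0] = b[0];
  for (int i = 1; i < n; ++i) {
    denom[i] = b[i] - a[i] * cp[i - 1];
    cp[i] = c[i] / denom[i];
  }

  std::vector<char> above(n, 0);
  for (int i = 0; i < n; ++i)
    above[i] = states(0, i) > event_thresh;
  std::vector<double> ev_t;
  std::vector<int> ev_node;

  NumericVector pv(12);
  for (int k = 0; k < 8; ++k) pv[k + 1] = gate_params[k];
  pv[10] = cell_type;
  pv[11] = gate_params.size() > 8 ? gate_params[8] : 0.0;

  int ir = 0;
  for (int q = 0; q < np; ++q) traces(0, q) = states(0, probe_nodes[q]);
  tvec[0] = 0.0;
  ir = 1;
  for (int nstp = 0; nstp < nstep; ++nstp) {
    double t = nstp * tau;
    double amp = stim_at(t, stim_t0, stim_dur, stim_amp);
    std::fill(istim.begin(), istim.end(), 0.0);
    if (amp != 0.0)
      for (int k = 0; k < stim_nodes.size(); ++k) istim[stim_nodes[k]] = amp;
    // ODE stage + assemble rhs
    for (int i = 0; i < n; ++i) {
      pv[0] = rho.size() == 1 ? rho[0] : rho[i];
      pv[9] = iks_factor.size() == 1 ? iks_factor[0] : iks_factor[i];
      CellP p = unpack_params(pv);
      double *s = &states(0, i);
      double iion = tp06_ode_step(s, p, tau, istim[i]);
      rhs[i] = s[0] + tau * (-iion + istim[i]);
    }
    // Thomas solve
    v[0] = rhs[0] / denom[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] - a[i] * v[i - 1]) / denom[i];
    for (int i = n - 2; i >= 0; --i) v[i] -= cp[i] * v[i + 1];
    for (int i = 0; i < n; ++i) {
      double vold = states(0, i);
      double vnew = v[i];
      if (!std::isfinite(vnew))
        stop("non-finite membrane potential at t = %f ms, node %d", t, i + 1);
      if (!above[i] && vnew > event_thresh &&
          (vnew - vold) / tau > event_slope) {
        above[i] = 1;
        ev_t.push_back(t + tau);
        ev_node.push_back(i + 1);
      } else if (above[i] && vnew < event_thresh - 10.0) {
        above[i] = 0;
      }
      states(0, i) = vnew;
    }
    if ((nstp + 1) % every == 0 && ir < nrec) {
      for (int q = 0; q < np; ++q) traces(ir, q) = states(0, probe_nodes[q]);
      tvec[ir] = (nstp + 1) * tau;
      ++ir;
    }
  }
  return List::create(
      _["time"] = tvec, _["traces"] = traces, _["final_states"] = states,
      _["events"] = DataFrame::create(_["node"] = wrap(ev_node),
                                      _["time"] = wrap(ev_t)));
}
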