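// Adult human atrial ionic model (Courtemanche, Ramirez & Nattel 1998),
// transcribed from the published equation set. Units: mV, ms, pA/pF
// (== mV/ms on Vm), concentrations in mM. Quiescent without stimulus.

#include "models.h"

namespace cardiomod {
namespace atrial {

constexpr double F = 96.4867;     // C/mmol
constexpr double Rgas = 8.3143;   // J/(mol K)
constexpr double Temp = 310.0;    // K
const double RTF = Rgas * Temp / F;    // mV
const double FRT = 1.0 / RTF;          // 1/mV

constexpr double Cm = 100.0;      // pF
constexpr double Vi = 13668.0;    // um^3
constexpr double Vup = 1109.52;
constexpr double Vrel = 96.48;

constexpr double Ko = 5.4, Nao = 140.0, Cao = 1.8;

constexpr double gNa = 7.8;            // nS/pF
constexpr double gK1 = 0.09;
constexpr double gto = 0.1652;
constexpr double gKr = 0.029411765;
constexpr double gKs = 0.12941176;
constexpr double gCaL = 0.12375;
constexpr double gbCa = 0.001131;
constexpr double gbNa = 0.0006744375;
constexpr double INaK_max = 0.59933874;
constexpr double KmNai_nak = 10.0, KmKo = 1.5;
constexpr double INaCa_max = 1600.0;
constexpr double KmNa_ncx = 87.5, KmCa_ncx = 1.38;
constexpr double ksat = 0.1, gamma_ncx = 0.35;
constexpr double IpCa_max = 0.275;
constexpr double krel = 30.0;          // 1/ms
constexpr double Iup_max = 0.005;      // mM/ms
constexpr double Kup = 0.00092;
constexpr double Caup_max = 15.0;
constexpr double tau_tr = 180.0;       // ms
constexpr double KQ10 = 3.0;
constexpr double TRPN_max = 0.07, KmTRPN = 0.0005;
constexpr double CMDN_max = 0.05, KmCMDN = 0.00238;
constexpr double CSQN_max = 10.0, KmCSQN = 0.8;

enum { iV = 0, im, ih, ij, ioa, ioi, iua, iui, ixr, ixs, id, iff, ifca,
       iu, ivg, iw, iNai, iKi, iCai, iCaup, iCarel, N_STATE };
constexpr int N_GATE = 15;

static const char* NAMES[N_STATE] = {
  "v", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fca",
  "u", "vrel", "w", "Nai", "Ki", "Cai", "Caup", "Carel"};

static void initial_state(double* y) {
  y[iV] = -81.18;
  y[im] = 0.002908; y[ih] = 0.9649; y[ij] = 0.9775;
  y[ioa] = 0.03043; y[ioi] = 0.9992;
  y[iua] = 0.004966; y[iui] = 0.9986;
  y[ixr] = 3.296e-5; y[ixs] = 0.01869;
  y[id] = 1.367e-4; y[iff] = 0.9996; y[ifca] = 0.7755;
  y[iu] = 0.0; y[ivg] = 1.0; y[iw] = 0.9992;
  y[iNai] = 11.17; y[iKi] = 139.0; y[iCai] = 1.013e-4;
  y[iCaup] = 1.488; y[iCarel] = 1.488;
}

// ---- gate kinetics (v in mV, tau in ms) ----

static double m_a(double v) {
  if (std::fabs(v + 47.13) < 1e-6) return 3.2;
  return 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
}
static double m_b(double v) { return 0.08 * std::exp(-v / 11.0); }
static double m_inf(double v) { return m_a(v) / (m_a(v) + m_b(v)); }
static double m_tau(double v) { return 1.0 / (m_a(v) + m_b(v)); }

static double h_a(double v) {
  return v >= -40.0 ? 0.0 : 0.135 * std::exp(-(v + 80.0) / 6.8);
}
static double h_b(double v) {
  if (v >= -40.0)
    return 1.0 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
  return 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
}
static double h_inf(double v) { return h_a(v) / (h_a(v) + h_b(v)); }
static double h_tau(double v) { return 1.0 / (h_a(v) + h_b(v)); }

static double j_a(double v) {
  if (v >= -40.0) return 0.0;
  return (-1.2714e5 * std::exp(0.2444 * v) - 3.474e-5 * std::exp(-0.04391 * v)) *
         (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
}
static double j_b(double v) {
  if (v >= -40.0)
    return 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  return 0.1212 * std::exp(-0.01052 * v) /
         (1.0 + std::exp(-0.1378 * (v + 40.14)));
}
static double j_inf(double v) { return j_a(v) / (j_a(v) + j_b(v)); }
static double j_tau(double v) { return 1.0 / (j_a(v) + j_b(v)); }

static double oa_ab(double v, bool beta) {
  if (beta) return 0.65 / (2.5 + std::exp((v + 82.0) / 17.0));
  return 0.65 / (std::exp(-(v + 10.0) / 8.5) + std::exp(-(v - 30.0) / 59.0));
}
static double oa_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 20.47) / 17.54)); }
static double oa_tau(double v) { return 1.0 / ((oa_ab(v, false) + oa_ab(v, true)) * KQ10); }
static double oi_inf(double v) { return 1.0 / (1.0 + std::exp((v + 43.1) / 5.3)); }
static double oi_tau(double v) {
  double a = 1.0 / (18.53 + std::exp((v + 113.7) / 10.95));
  double b = 1.0 / (35.56 + std::exp(-(v + 1.26) / 7.44));
  return 1.0 / ((a + b) * KQ10);
}
static double ua_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 30.3) / 9.6)); }
static double ua_tau(double v) { return oa_tau(v); }  // shared rate constants
static double ui_inf(double v) { return 1.0 / (1.0 + std::exp((v - 99.45) / 27.48)); }
static double ui_tau(double v) {
  double a = 1.0 / (21.0 + std::exp(-(v - 185.0) / 28.0));
  double b = std::exp((v - 158.0) / 16.0);
  return 1.0 / ((a + b) * KQ10);
}
static double xr_a(double v) {
  if (std::fabs(v + 14.1) < 1e-6) return 0.0015;
  return 0.0003 * (v + 14.1) / (1.0 - std::exp(-(v + 14.1) / 5.0));
}
static double xr_b(double v) {
  if (std::fabs(v - 3.3328) < 1e-6) return 3.7836118e-4;
  return 7.3898e-5 * (v - 3.3328) / (std::exp((v - 3.3328) / 5.1237) - 1.0);
}
static double xr_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 14.1) / 6.5)); }
static double xr_tau(double v) { return 1.0 / (xr_a(v) + xr_b(v)); }
static double xs_a(double v) {
  if (std::fabs(v - 19.9) < 1e-6) return 6.8e-4;
  return 4e-5 * (v - 19.9) / (1.0 - std::exp(-(v - 19.9) / 17.0));
}
static double xs_b(double v) {
  if (std::fabs(v - 19.9) < 1e-6) return 3.15e-4;
  return 3.5e-5 * (v - 19.9) / (std::exp((v - 19.9) / 9.0) - 1.0);
}
static double xs_inf(double v) { return 1.0 / std::sqrt(1.0 + std::exp(-(v - 19.9) / 12.7)); }
static double xs_tau(double v) { return 0.5 / (xs_a(v) + xs_b(v)); }
static double d_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 10.0) / 8.0)); }
static double d_tau(double v) {
  if (std::fabs(v + 10.0) < 1e-6) return 4.579 / (1.0 + std::exp(-(v + 10.0) / 6.24));
  double e = std::exp(-(v + 10.0) / 6.24);
  return (1.0 - e) / (0.035 * (v + 10.0) * (1.0 + e));
}
static double f_inf(double v) { return 1.0 / (1.0 + std::exp((v + 28.0) / 6.9)); }
static double f_tau(double v) {
  return 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (v + 10.0) * (v + 10.0)) + 0.02);
}
static double w_inf(double v) { return 1.0 - 1.0 / (1.0 + std::exp(-(v - 40.0) / 17.0)); }
static double w_tau(double v) {
  if (std::fabs(v - 7.9) < 1e-6) return 6.0 * 0.2 / 1.3;
  double e = std::exp(-(v - 7.9) / 5.0);
  return 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (v - 7.9));
}

static double fnak_of(double v) {
  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  return 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * FRT * v) +
                0.0365 * sigma * std::exp(-FRT * v));
}

// ---- full analytic right-hand side ----
static double rhs(const double* y, double* dy, double s_na, double s_nak,
                  double istim) {
  double v = y[iV];
  double Nai = y[iNai], Kii = y[iKi], Cai = y[iCai];
  double Caup = y[iCaup], Carel = y[iCarel];

  double ENa = RTF * std::log(Nao / Nai);
  double EK = RTF * std::log(Ko / Kii);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  double INa = s_na * gNa * y[im] * y[im] * y[im] * y[ih] * y[ij] * (v - ENa);
  double IK1 = gK1 * (v - EK) / (1.0 + std::exp(0.07 * (v + 80.0)));
  double Ito = gto * y[ioa] * y[ioa] * y[ioa] * y[ioi] * (v - EK);
  double gKur = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
  double IKur = gKur * y[iua] * y[iua] * y[iua] * y[iui] * (v - EK);
  double IKr = gKr * y[ixr] * (v - EK) / (1.0 + std::exp((v + 15.0) / 22.4));
  double IKs = gKs * y[ixs] * y[ixs] * (v - EK);
  double ICaL = gCaL * y[id] * y[iff] * y[ifca] * (v - 65.0);
  double INaK = s_nak * INaK_max * fnak_of(v) /
      (1.0 + std::pow(KmNai_nak / Nai, 1.5)) * Ko / (Ko + KmKo);
  double e1 = std::exp(gamma_ncx * FRT * v);
  double e2 = std::exp((gamma_ncx - 1.0) * FRT * v);
  double INaCa = INaCa_max *
      (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai) /
      ((KmNa_ncx * KmNa_ncx * KmNa_ncx + Nao * Nao * Nao) *
       (KmCa_ncx + Cao) * (1.0 + ksat * e2));
  double IbNa = gbNa * (v - ENa);
  double IbCa = gbCa * (v - ECa);
  double IpCa = IpCa_max * Cai / (0.0005 + Cai);

  double itot = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
                INaCa + IbNa + IbCa;
  dy[iV] = -itot + istim;

  dy[im] = (m_inf(v) - y[im]) / m_tau(v);
  dy[ih] = (h_inf(v) - y[ih]) / h_tau(v);
  dy[ij] = (j_inf(v) - y[ij]) / j_tau(v);
  dy[ioa] = (oa_inf(v) - y[ioa]) / oa_tau(v);
  dy[ioi] = (oi_inf(v) - y[ioi]) / oi_tau(v);
  dy[iua] = (ua_inf(v) - y[iua]) / ua_tau(v);
  dy[iui] = (ui_inf(v) - y[iui]) / ui_tau(v);
  dy[ixr] = (xr_inf(v) - y[ixr]) / xr_tau(v);
  dy[ixs] = (xs_inf(v) - y[ixs]) / xs_tau(v);
  dy[id] = (d_inf(v) - y[id]) / d_tau(v);
  dy[iff] = (f_inf(v) - y[iff]) / f_tau(v);
  double fca_inf = 1.0 / (1.0 + Cai / 0.00035);
  dy[ifca] = (fca_inf - y[ifca]) / 2.0;
  dy[iw] = (w_inf(v) - y[iw]) / w_tau(v);

  double Irel = krel * y[iu] * y[iu] * y[ivg] * y[iw] * (Carel - Cai);
  double Fn = 1e-12 * Vrel * Irel -
              (5e-13 / F) * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);
  double u_inf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tau_v = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  dy[iu] = (u_inf - y[iu]) / 8.0;
  dy[ivg] = (v_inf - y[ivg]) / tau_v;

  double Iup = Iup_max / (1.0 + Kup / Cai);
  double Iupleak = Iup_max * Caup / Caup_max;
  double Itr = (Caup - Carel) / tau_tr;

  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * F * Vi) +
              (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double B2 = 1.0 + TRPN_max * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
              CMDN_max * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));
  dy[iCai] = B1 / B2;
  dy[iCaup] = Iup - Iupleak - Itr * Vrel / Vup;
  dy[iCarel] = (Itr - Irel) /
      (1.0 + CSQN_max * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));
  dy[iNai] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (F * Vi);
  dy[iKi] = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / (F * Vi);
  return itot;
}

// ---- tabulated Rush-Larsen stepping ----

static const int TAB_GATES[12] = {im, ih, ij, ioa, ioi, iua, iui, ixr, ixs,
                                  id, iff, iw};
typedef double (*vfun)(double);
static const vfun TAB_INF[12] = {m_inf, h_inf, j_inf, oa_inf, oi_inf, ua_inf,
                                 ui_inf, xr_inf, xs_inf, d_inf, f_inf, w_inf};
static const vfun TAB_TAU[12] = {m_tau, h_tau, j_tau, oa_tau, oi_tau, ua_tau,
                                 ui_tau, xr_tau, xs_tau, d_tau, f_tau, w_tau};

// interleaved row slots: [inf,rl] x 12 gates, then aux
enum { S_FNAK = 24, S_NCX1, S_NCX2, S_IK1D, S_XRR, S_GKUR, N_SLOT };
enum { SL_ENA = 0, SL_EK, SL_ECA, SL_UINF, SL_VINF, SL_RLV, N_SLOW };
enum { C_RLFCA = 0, C_RLU };

static const double NCX_DEN0 =
    (KmNa_ncx * KmNa_ncx * KmNa_ncx + Nao * Nao * Nao) * (KmCa_ncx + Cao);

static void build_tables(Tables& T, double dt) {
  int n = static_cast<int>(std::round((TAB_VMAX - TAB_VMIN) / TAB_DV)) + 1;
  T.dt = dt; T.n = n; T.stride = N_SLOT;
  T.vmin = TAB_VMIN; T.dv_inv = 1.0 / TAB_DV;
  T.flat.assign(static_cast<size_t>(n) * N_SLOT, 0.0);
  for (int k = 0; k < n; ++k) {
    double v = TAB_VMIN + k * TAB_DV;
    double* row = T.flat.data() + static_cast<size_t>(k) * N_SLOT;
    for (int gi = 0; gi < 12; ++gi) {
      row[2 * gi] = TAB_INF[gi](v);
      row[2 * gi + 1] = -std::expm1(-dt / TAB_TAU[gi](v));
    }
    row[S_FNAK] = fnak_of(v);
    row[S_NCX1] = std::exp(gamma_ncx * FRT * v);
    row[S_NCX2] = std::exp((gamma_ncx - 1.0) * FRT * v);
    row[S_IK1D] = 1.0 / (1.0 + std::exp(0.07 * (v + 80.0)));
    row[S_XRR] = 1.0 / (1.0 + std::exp((v + 15.0) / 22.4));
    row[S_GKUR] = 0.005 + 0.05 / (1.0 + std::exp(-(v - 15.0) / 13.0));
  }
  T.consts.assign(2, 0.0);
  T.consts[C_RLFCA] = -std::expm1(-dt / 2.0);
  T.consts[C_RLU] = -std::expm1(-dt / 8.0);
}

static void refresh_slow(const double* y, SlowCache& S, size_t el, double dt,
                         const Tables& T, bool heavy) {
  double* s = S.at(el);
  double v = y[iV];
  double Nai = y[iNai], Cai = y[iCai], Carel = y[iCarel];
  if (Cai < 1e-9) Cai = 1e-9;
  // light: calcium-release trigger (Fn) gates
  TabRow row = tab_row(T, v);
  double ICaL = gCaL * y[id] * y[iff] * y[ifca] * (v - 65.0);
  double e2 = row(S_NCX2);
  double INaCa = INaCa_max *
      (row(S_NCX1) * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai) /
      (NCX_DEN0 * (1.0 + ksat * e2));
  double Irel = krel * y[iu] * y[iu] * y[ivg] * y[iw] * (Carel - Cai);
  double Fn = 1e-12 * Vrel * Irel -
              (5e-13 / F) * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);
  double eu = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  s[SL_UINF] = 1.0 / (1.0 + eu);
  s[SL_VINF] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  s[SL_RLV] = -std::expm1(-dt / tau_v);
  if (!heavy) return;
  // heavy: Nernst potentials (intracellular concentrations drift slowly)
  double Kii = y[iKi];
  if (Nai < 1e-3) Nai = 1e-3;
  if (Kii < 1e-3) Kii = 1e-3;
  s[SL_ENA] = RTF * std::log(Nao / Nai);
  s[SL_EK] = RTF * std::log(Ko / Kii);
  s[SL_ECA] = 0.5 * RTF * std::log(Cao / Cai);
}

static void step(double* y, double dt, const Tables& T, const SlowCache& S,
                 size_t el, double s_na, double s_nak, double istim,
                 long* clamped) {
  const double* s = S.at(el);
  double v = y[iV];
  TabRow row = tab_row(T, v);

  for (int gi = 0; gi < 12; ++gi) {
    int si = TAB_GATES[gi];
    y[si] = clamp_gate(y[si] + (row(2 * gi) - y[si]) * row(2 * gi + 1),
                       clamped);
  }
  double Cai = y[iCai];
  double fca_inf = 1.0 / (1.0 + Cai / 0.00035);
  y[ifca] = clamp_gate(y[ifca] + (fca_inf - y[ifca]) * T.consts[C_RLFCA],
                       clamped);
  y[iu] = clamp_gate(y[iu] + (s[SL_UINF] - y[iu]) * T.consts[C_RLU], clamped);
  y[ivg] = clamp_gate(y[ivg] + (s[SL_VINF] - y[ivg]) * s[SL_RLV], clamped);

  double Nai = y[iNai], Kii = y[iKi];
  double Caup = y[iCaup], Carel = y[iCarel];

  double INa = s_na * gNa * y[im] * y[im] * y[im] * y[ih] * y[ij] *
               (v - s[SL_ENA]);
  double IK1 = gK1 * (v - s[SL_EK]) * row(S_IK1D);
  double Ito = gto * y[ioa] * y[ioa] * y[ioa] * y[ioi] * (v - s[SL_EK]);
  double IKur = row(S_GKUR) * y[iua] * y[iua] * y[iua] *
                y[iui] * (v - s[SL_EK]);
  double IKr = gKr * y[ixr] * (v - s[SL_EK]) * row(S_XRR);
  double IKs = gKs * y[ixs] * y[ixs] * (v - s[SL_EK]);
  double ICaL = gCaL * y[id] * y[iff] * y[ifca] * (v - 65.0);
  double xn = KmNai_nak / Nai;
  double nai_fac = 1.0 / (1.0 + xn * std::sqrt(xn));  // (KmNai/Nai)^1.5
  double INaK = s_nak * INaK_max * row(S_FNAK) * nai_fac *
                Ko / (Ko + KmKo);
  double e2 = row(S_NCX2);
  double INaCa = INaCa_max *
      (row(S_NCX1) * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai) /
      (NCX_DEN0 * (1.0 + ksat * e2));
  double IbNa = gbNa * (v - s[SL_ENA]);
  double IbCa = gbCa * (v - s[SL_ECA]);
  double IpCa = IpCa_max * Cai / (0.0005 + Cai);

  double itot = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
                INaCa + IbNa + IbCa;

  double Irel = krel * y[iu] * y[iu] * y[ivg] * y[iw] * (Carel - Cai);
  double Iup = Iup_max / (1.0 + Kup / Cai);
  double Iupleak = Iup_max * Caup / Caup_max;
  double Itr = (Caup - Carel) / tau_tr;

  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * F * Vi) +
              (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double B2 = 1.0 + TRPN_max * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
              CMDN_max * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));

  y[iV] = v + dt * (-itot + istim);
  y[iCai] = Cai + dt * B1 / B2;
  if (y[iCai] < 1e-9) y[iCai] = 1e-9;
  y[iCaup] = Caup + dt * (Iup - Iupleak - Itr * Vrel / Vup);
  y[iCarel] = Carel + dt * (Itr - Irel) /
      (1.0 + CSQN_max * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));
  if (y[iCarel] < 1e-9) y[iCarel] = 1e-9;
  y[iNai] = Nai + dt * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (F * Vi);
  y[iKi] = Kii + dt * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / (F * Vi);
}

}  // namespace atrial

const ModelDef& model_def_atrial() {
  static const ModelDef def = {
      atrial::N_STATE, atrial::N_GATE, atrial::N_SLOW, atrial::NAMES,
      atrial::initial_state, atrial::rhs, atrial::build_tables,
      atrial::refresh_slow, atrial::step};
  return def;
}

}  // namespace cardiomod
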