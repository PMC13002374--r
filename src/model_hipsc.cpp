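// Spontaneously beating hiPSC-CM ionic model (Paci et al. 2013,
// ventricular-like spontaneous variant), transcribed from the published
// equation set. Internally the published SI formulation (volts, seconds) is
// mapped onto the package convention (mV, ms); note 1 V/s == 1 mV/ms, so
// currents in A/F feed dVm/dt unchanged.

#include "models.h"

namespace cardiomod {
namespace hipsc {

// physical constants
constexpr double F = 96485.3415;       // C/mol
constexpr double Rgas = 8.314472;      // J/(mol K)
constexpr double Temp = 310.0;         // K
const double RTF = Rgas * Temp / F;    // V

// geometry / capacitance
constexpr double Cm = 9.87109e-11;     // F
constexpr double Vc = 8800.0;          // um^3
constexpr double V_SR = 583.73;        // um^3

// external / fixed concentrations (mM)
constexpr double Nao = 151.0;
constexpr double Ko = 5.4;
constexpr double Cao = 1.8;
constexpr double Ki = 150.0;

// maximal conductances and fluxes (ventricular-like variant)
constexpr double GNa = 3671.2302;      // S/F
constexpr double Gf = 30.10312;        // S/F
constexpr double Ef = -0.017;          // V
constexpr double gCaL = 8.635702e-5;   // m^3/(F s)
constexpr double Gto = 29.9038;        // S/F
constexpr double Gks = 2.041;          // S/F
constexpr double Gkr = 29.8667;        // S/F
constexpr double GK1 = 28.1492;        // S/F
constexpr double kNaCa = 4900.0;       // A/F
constexpr double alpha_ncx = 2.8571432;
constexpr double gamma_ncx = 0.35;
constexpr double Ksat = 0.1;
constexpr double KmCa = 1.38;
constexpr double KmNai = 87.5;
constexpr double PNaK = 1.841424;      // A/F
constexpr double Km_K = 1.0;
constexpr double Km_Na = 40.0;
constexpr double GpCa = 0.4125;        // A/F
constexpr double KpCa = 0.0005;
constexpr double GbNa = 0.9;           // S/F
constexpr double GbCa = 0.69264;       // S/F
constexpr double PkNa = 0.03;

// calcium handling
constexpr double a_rel = 16.464;       // mM/s
constexpr double b_rel = 0.25;
constexpr double c_rel = 8.232;
constexpr double VmaxUp = 0.56064;     // mM/s
constexpr double Kup = 0.00025;
constexpr double V_leak = 4.4444e-4;   // 1/s
constexpr double Buf_C = 0.25, Kbuf_C = 0.001;
constexpr double Buf_SR = 10.0, Kbuf_SR = 0.3;

// state indices
enum { iV = 0, im, ih, ij, id, if1, if2, ifCa, iXr1, iXr2, iXs, iXf, iq, ir,
       ig, iNai, iCai, iCaSR, N_STATE };
constexpr int N_GATE = 14;

static const char* NAMES[N_STATE] = {
  "v", "m", "h", "j", "d", "f1", "f2", "fCa", "Xr1", "Xr2", "Xs", "Xf",
  "q", "r", "g", "Nai", "Cai", "CaSR"};

// published initial state (settles onto the spontaneous limit cycle)
static void initial_state(double* y) {
  y[iV] = -74.3340057623841;
  y[im] = 0.102953468725004;
  y[ih] = 0.786926637881461;
  y[ij] = 0.253943221774722;
  y[id] = 8.96088425225182e-5;
  y[if1] = 0.970411811263976;
  y[if2] = 0.999965815466749;
  y[ifCa] = 0.998925296531804;
  y[iXr1] = 0.00778547011240132;
  y[iXr2] = 0.432162576531617;
  y[iXs] = 0.0322944866983666;
  y[iXf] = 0.100615100568753;
  y[iq] = 0.839295925773219;
  y[ir] = 0.00573289893326379;
  y[ig] = 0.999999981028517;
  y[iNai] = 10.9248496211574;
  y[iCai] = 1.80773974140477e-5;
  y[iCaSR] = 0.2734234751931;
}

// ---- gate kinetics (v in mV, tau in ms) ----

static double m_inf(double v) { return std::pow(1.0 + std::exp((-v - 34.1) / 5.9), -1.0 / 3.0); }
static double m_tau(double v) {
  double a = 1.0 / (1.0 + std::exp((-v - 60.0) / 5.0));
  double b = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
             0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
  return a * b;
}
static double h_inf(double v) { return 1.0 / std::sqrt(1.0 + std::exp((v + 72.1) / 5.7)); }
static double h_tau(double v) {
  if (v < -40.0) {
    double a = 0.057 * std::exp(-(v + 80.0) / 6.8);
    double b = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
    return 1.5 / (a + b);
  }
  return 2.542;
}
static double j_inf(double v) { return h_inf(v); }
static double j_tau(double v) {
  double a, b;
  if (v < -40.0) {
    a = (-25428.0 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v)) *
        (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
    b = 0.02424 * std::exp(-0.01052 * v) /
        (1.0 + std::exp(-0.1378 * (v + 40.14)));
  } else {
    a = 0.0;
    b = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  }
  return 7.0 / (a + b);
}
static double d_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 9.1) / 7.0)); }
static double d_tau(double v) {
  double a = 0.25 + 1.4 / (1.0 + std::exp((-v - 35.0) / 13.0));
  double b = 1.4 / (1.0 + std::exp((v + 5.0) / 5.0));
  double c = 1.0 / (1.0 + std::exp((-v + 50.0) / 20.0));
  return a * b + c;
}
static double f1_inf(double v) { return 1.0 / (1.0 + std::exp((v + 26.0) / 3.0)); }
static double f1_tau(double v) {
  double s = (v + 27.0) * (v + 27.0) / 15.0;
  return 20.0 + 1102.5 * std::exp(-s * s) +
         200.0 / (1.0 + std::exp((13.0 - v) / 10.0)) +
         180.0 / (1.0 + std::exp((30.0 + v) / 10.0));
}
static double f2_inf(double v) { return 0.33 + 0.67 / (1.0 + std::exp((v + 35.0) / 4.0)); }
static double f2_tau(double v) {
  return 600.0 * std::exp(-(v + 25.0) * (v + 25.0) / 170.0) +
         31.0 / (1.0 + std::exp((25.0 - v) / 10.0)) +
         16.0 / (1.0 + std::exp((30.0 + v) / 10.0));
}
static double xr1_inf(double v) {
  const double L0 = 0.025, Q = 2.3;
  double vhalf = 1000.0 * (-RTF / Q *
                 std::log(std::pow(1.0 + Cao / 2.6, 4.0) /
                          (L0 * std::pow(1.0 + Cao / 0.58, 4.0))) - 0.019);
  return 1.0 / (1.0 + std::exp((vhalf - v) / 4.9));
}
static double xr1_tau(double v) {
  double a = 450.0 / (1.0 + std::exp((-45.0 - v) / 10.0));
  double b = 6.0 / (1.0 + std::exp((v + 30.0) / 11.5));
  return a * b;
}
static double xr2_inf(double v) { return 1.0 / (1.0 + std::exp((v + 88.0) / 50.0)); }
static double xr2_tau(double v) {
  double a = 3.0 / (1.0 + std::exp((-60.0 - v) / 20.0));
  double b = 1.12 / (1.0 + std::exp((v - 60.0) / 20.0));
  return a * b;
}
static double xs_inf(double v) { return 1.0 / (1.0 + std::exp((-v - 20.0) / 16.0)); }
static double xs_tau(double v) {
  double a = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - v) / 6.0));
  double b = 1.0 / (1.0 + std::exp((v - 60.0) / 20.0));
  return a * b;
}
static double xf_inf(double v) { return 1.0 / (1.0 + std::exp((v + 77.85) / 5.0)); }
static double xf_tau(double v) { return 1900.0 / (1.0 + std::exp((v + 15.0) / 10.0)); }
static double q_inf(double v) { return 1.0 / (1.0 + std::exp((v + 53.0) / 13.0)); }
static double q_tau(double v) {
  return 6.06 + 39.102 / (0.57 * std::exp(-0.08 * (v + 44.0)) +
                          0.065 * std::exp(0.1 * (v + 45.93)));
}
static double r_inf(double v) { return 1.0 / (1.0 + std::exp(-(v - 22.3) / 18.75)); }
static double r_tau(double v) {
  return 2.75352 + 14.40516 / (1.037 * std::exp(0.09 * (v + 30.61)) +
                               0.369 * std::exp(-0.12 * (v + 23.84)));
}

// calcium-dependent steady states (integer powers unrolled: hot path)
static double fca_inf_of(double cai) {
  double x = cai / 0.0006;
  double x2 = x * x, x4 = x2 * x2, x8 = x4 * x4;
  double a = 1.0 / (1.0 + x8);
  double b = 0.1 / (1.0 + std::exp((cai - 0.0009) / 0.0001));
  double c = 0.3 / (1.0 + std::exp((cai - 0.00075) / 0.0008));
  return (a + b + c) / 1.3156;
}
static double g_inf_of(double cai) {
  double r = cai / 0.00035;
  double r2 = r * r, r4 = r2 * r2, r8 = r4 * r4;
  return cai <= 0.00035 ? 1.0 / (1.0 + r2 * r4)
                        : 1.0 / (1.0 + r8 * r8);
}

static const double EK = RTF * std::log(Ko / Ki);  // V, Ki fixed

// inward-rectifier open probability (v, EK in mV units inside)
static double xk1_inf(double v) {
  double vk = v - EK * 1000.0;
  double a = 3.91 / (1.0 + std::exp(0.5942 * (vk - 200.0)));
  double b = (-1.509 * std::exp(0.0002 * (vk + 100.0)) +
              std::exp(0.5886 * (vk - 10.0))) /
             (1.0 + std::exp(0.4547 * vk));
  return a / (a + b);
}

// GHK-style flux coefficients for the L-type current:
// ICaL = gCaL d f1 f2 fCa (A(v) Cai - B(v) Cao)
static void ical_coef(double v, double& A, double& B) {
  double VV = v * 1e-3;
  double x = 2.0 * VV * F / (Rgas * Temp);
  if (std::fabs(x) < 1e-7) {
    A = 2.0 * F;
    B = 2.0 * F * 0.341;
    return;
  }
  double ex = std::exp(x);
  double pre = 2.0 * F * x;  // == 4 VV F^2 / (R T)
  A = pre * ex / (ex - 1.0);
  B = pre * 0.341 / (ex - 1.0);
}

// ---- full analytic right-hand side ----
static double rhs(const double* y, double* dy, double s_na, double s_nak,
                  double istim) {
  double v = y[iV], VV = v * 1e-3;
  double Nai = y[iNai], Cai = y[iCai], CaSR = y[iCaSR];

  double ENa = RTF * std::log(Nao / Nai);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);
  double EKs = RTF * std::log((Ko + PkNa * Nao) / (Ki + PkNa * Nai));

  double INa = s_na * GNa * y[im] * y[im] * y[im] * y[ih] * y[ij] * (VV - ENa);
  double If = Gf * y[iXf] * (VV - Ef);
  double A, B;
  ical_coef(v, A, B);
  double ICaL = gCaL * y[id] * y[if1] * y[if2] * y[ifCa] * (A * Cai - B * Cao);
  double Ito = Gto * y[iq] * y[ir] * (VV - EK);
  double iks_fac = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / Cai, 1.4));
  double IKs = Gks * y[iXs] * y[iXs] * iks_fac * (VV - EKs);
  double IKr = Gkr * std::sqrt(Ko / 5.4) * y[iXr1] * y[iXr2] * (VV - EK);
  double IK1 = GK1 * std::sqrt(Ko / 5.4) * xk1_inf(v) * (VV - EK);
  double e1 = std::exp(gamma_ncx * VV * F / (Rgas * Temp));
  double e2 = std::exp((gamma_ncx - 1.0) * VV * F / (Rgas * Temp));
  double INaCa = kNaCa *
      (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai * alpha_ncx) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + Ksat * e2));
  double INaK = s_nak * PNaK * (Ko / (Ko + Km_K)) * (Nai / (Nai + Km_Na)) /
      (1.0 + 0.1245 * std::exp(-0.1 * VV * F / (Rgas * Temp)) +
       0.0353 * std::exp(-VV * F / (Rgas * Temp)));
  double IpCa = GpCa * Cai / (Cai + KpCa);
  double IbNa = GbNa * (VV - ENa);
  double IbCa = GbCa * (VV - ECa);

  double itot = INa + If + ICaL + Ito + IKs + IKr + IK1 + INaCa + INaK +
                IpCa + IbNa + IbCa;
  dy[iV] = -itot + istim;

  // gates (d/dt in 1/ms)
  dy[im] = (m_inf(v) - y[im]) / m_tau(v);
  dy[ih] = (h_inf(v) - y[ih]) / h_tau(v);
  dy[ij] = (j_inf(v) - y[ij]) / j_tau(v);
  dy[id] = (d_inf(v) - y[id]) / d_tau(v);
  double cf1 = (f1_inf(v) - y[if1] > 0.0) ? 1.0 + 1433.0 * (Cai - 50.0e-6) : 1.0;
  dy[if1] = (f1_inf(v) - y[if1]) / (f1_tau(v) * cf1);
  dy[if2] = (f2_inf(v) - y[if2]) / f2_tau(v);
  double fcai = fca_inf_of(Cai);
  dy[ifCa] = (v > -60.0 && fcai > y[ifCa]) ? 0.0 : (fcai - y[ifCa]) / 2.0;
  dy[iXr1] = (xr1_inf(v) - y[iXr1]) / xr1_tau(v);
  dy[iXr2] = (xr2_inf(v) - y[iXr2]) / xr2_tau(v);
  dy[iXs] = (xs_inf(v) - y[iXs]) / xs_tau(v);
  dy[iXf] = (xf_inf(v) - y[iXf]) / xf_tau(v);
  dy[iq] = (q_inf(v) - y[iq]) / q_tau(v);
  dy[ir] = (r_inf(v) - y[ir]) / r_tau(v);
  double gi = g_inf_of(Cai);
  dy[ig] = (v > -60.0 && gi > y[ig]) ? 0.0 : (gi - y[ig]) / 2.0;

  // calcium handling (published rates are mM/s; convert to mM/ms)
  double Irel = (c_rel + a_rel * CaSR * CaSR / (b_rel * b_rel + CaSR * CaSR)) *
                y[id] * y[ig] * 0.0411;
  double Iup = VmaxUp / (1.0 + Kup * Kup / (Cai * Cai));
  double Ileak = (CaSR - Cai) * V_leak;
  double cai_buf = 1.0 / (1.0 + Buf_C * Kbuf_C / ((Cai + Kbuf_C) * (Cai + Kbuf_C)));
  double casr_buf = 1.0 / (1.0 + Buf_SR * Kbuf_SR / ((CaSR + Kbuf_SR) * (CaSR + Kbuf_SR)));
  double mem = (ICaL + IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * 1e-18 * F);
  dy[iCai] = 1e-3 * cai_buf * (Irel + Ileak - Iup - mem);
  dy[iCaSR] = 1e-3 * casr_buf * (Vc / V_SR) * (Iup - Irel - Ileak);
  dy[iNai] = 1e-3 * (-Cm * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) /
                     (F * Vc * 1e-18));
  return itot;
}

// ---- tabulated Rush-Larsen stepping ----

// gate table order (voltage-dependent gates; f1 stores inf and tau because
// its rl factor carries a calcium-dependent tau scaling via the slow cache)
static const int TAB_GATES[11] = {im, ih, ij, id, if2, iXr1, iXr2, iXs, iXf,
                                  iq, ir};
typedef double (*vfun)(double);
static const vfun TAB_INF[11] = {m_inf, h_inf, j_inf, d_inf, f2_inf, xr1_inf,
                                 xr2_inf, xs_inf, xf_inf, q_inf, r_inf};
static const vfun TAB_TAU[11] = {m_tau, h_tau, j_tau, d_tau, f2_tau, xr1_tau,
                                 xr2_tau, xs_tau, xf_tau, q_tau, r_tau};

// interleaved row slots: [inf,rl] x 11 gates, then f1 inf/tau, then aux
enum { S_F1INF = 22, S_F1TAU, S_INAK, S_NCX1, S_NCX2, S_ICALA, S_ICALB,
       S_IK1, N_SLOT };
// slow cache slots
enum { SL_ENA = 0, SL_ECA, SL_EKS, SL_RLF1, SL_IKSFAC, SL_FCAINF, SL_GINF,
       N_SLOW };
// consts slots
enum { C_RL2MS = 0 };

static const double NCX_DEN0 =
    (KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao);

static void build_tables(Tables& T, double dt) {
  int n = static_cast<int>(std::round((TAB_VMAX - TAB_VMIN) / TAB_DV)) + 1;
  T.dt = dt; T.n = n; T.stride = N_SLOT;
  T.vmin = TAB_VMIN; T.dv_inv = 1.0 / TAB_DV;
  T.flat.assign(static_cast<size_t>(n) * N_SLOT, 0.0);
  for (int k = 0; k < n; ++k) {
    double v = TAB_VMIN + k * TAB_DV;
    double* row = T.flat.data() + static_cast<size_t>(k) * N_SLOT;
    for (int gi = 0; gi < 11; ++gi) {
      row[2 * gi] = TAB_INF[gi](v);
      row[2 * gi + 1] = -std::expm1(-dt / TAB_TAU[gi](v));
    }
    row[S_F1INF] = f1_inf(v);
    row[S_F1TAU] = f1_tau(v);
    double VV = v * 1e-3;
    row[S_INAK] = 1.0 /
        (1.0 + 0.1245 * std::exp(-0.1 * VV * F / (Rgas * Temp)) +
         0.0353 * std::exp(-VV * F / (Rgas * Temp)));
    row[S_NCX1] = std::exp(gamma_ncx * VV * F / (Rgas * Temp));
    row[S_NCX2] = std::exp((gamma_ncx - 1.0) * VV * F / (Rgas * Temp));
    double A, B;
    ical_coef(v, A, B);
    row[S_ICALA] = A;
    row[S_ICALB] = B;
    row[S_IK1] = GK1 * std::sqrt(Ko / 5.4) * xk1_inf(v) * (VV - EK);
  }
  T.consts.assign(1, 0.0);
  T.consts[C_RL2MS] = -std::expm1(-dt / 2.0);
}

static void refresh_slow(const double* y, SlowCache& S, size_t el, double dt,
                         const Tables& T, bool heavy) {
  double* s = S.at(el);
  double Cai = y[iCai];
  if (Cai < 1e-9) Cai = 1e-9;
  // light: calcium-dependent gate targets (tau ~ 2 ms)
  s[SL_FCAINF] = fca_inf_of(Cai);
  s[SL_GINF] = g_inf_of(Cai);
  if (!heavy) return;
  // heavy: Nernst potentials and slow rate factors (drift over >= 1 ms)
  double Nai = y[iNai];
  if (Nai < 1e-3) Nai = 1e-3;
  s[SL_ENA] = RTF * std::log(Nao / Nai);
  s[SL_ECA] = 0.5 * RTF * std::log(Cao / Cai);
  s[SL_EKS] = RTF * std::log((Ko + PkNa * Nao) / (Ki + PkNa * Nai));
  TabRow row = tab_row(T, y[iV]);
  double cf1 = (row(S_F1INF) - y[if1] > 0.0)
      ? 1.0 + 1433.0 * (Cai - 50.0e-6) : 1.0;
  if (cf1 < 0.05) cf1 = 0.05;
  s[SL_RLF1] = -std::expm1(-dt / (row(S_F1TAU) * cf1));
  s[SL_IKSFAC] = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / Cai, 1.4));
}

static void step(double* y, double dt, const Tables& T, const SlowCache& S,
                 size_t el, double s_na, double s_nak, double istim,
                 long* clamped) {
  const double* s = S.at(el);
  double v = y[iV];
  TabRow row = tab_row(T, v);

  // Rush-Larsen gate updates (f1 uses the cached, calcium-scaled rl factor)
  for (int gi = 0; gi < 11; ++gi) {
    int si = TAB_GATES[gi];
    y[si] = clamp_gate(y[si] + (row(2 * gi) - y[si]) * row(2 * gi + 1),
                       clamped);
  }
  y[if1] = clamp_gate(y[if1] + (row(S_F1INF) - y[if1]) * s[SL_RLF1], clamped);
  double rl2 = T.consts[C_RL2MS];
  if (!(v > -60.0 && s[SL_FCAINF] > y[ifCa]))
    y[ifCa] = clamp_gate(y[ifCa] + (s[SL_FCAINF] - y[ifCa]) * rl2, clamped);
  if (!(v > -60.0 && s[SL_GINF] > y[ig]))
    y[ig] = clamp_gate(y[ig] + (s[SL_GINF] - y[ig]) * rl2, clamped);

  // currents
  double VV = v * 1e-3;
  double Nai = y[iNai], Cai = y[iCai], CaSR = y[iCaSR];
  double INa = s_na * GNa * y[im] * y[im] * y[im] * y[ih] * y[ij] *
               (VV - s[SL_ENA]);
  double If = Gf * y[iXf] * (VV - Ef);
  double ICaL = gCaL * y[id] * y[if1] * y[if2] * y[ifCa] *
      (row(S_ICALA) * Cai - row(S_ICALB) * Cao);
  double Ito = Gto * y[iq] * y[ir] * (VV - EK);
  double IKs = Gks * y[iXs] * y[iXs] * s[SL_IKSFAC] * (VV - s[SL_EKS]);
  double IKr = Gkr * y[iXr1] * y[iXr2] * (VV - EK);  // sqrt(Ko/5.4) = 1
  double IK1 = row(S_IK1);
  double e2 = row(S_NCX2);
  double INaCa = kNaCa *
      (row(S_NCX1) * Nai * Nai * Nai * Cao -
       e2 * Nao * Nao * Nao * Cai * alpha_ncx) /
      (NCX_DEN0 * (1.0 + Ksat * e2));
  double INaK = s_nak * PNaK * (Ko / (Ko + Km_K)) * (Nai / (Nai + Km_Na)) *
                row(S_INAK);
  double IpCa = GpCa * Cai / (Cai + KpCa);
  double IbNa = GbNa * (VV - s[SL_ENA]);
  double IbCa = GbCa * (VV - s[SL_ECA]);

  double itot = INa + If + ICaL + Ito + IKs + IKr + IK1 + INaCa + INaK +
                IpCa + IbNa + IbCa;

  // calcium handling
  double Irel = (c_rel + a_rel * CaSR * CaSR / (b_rel * b_rel + CaSR * CaSR)) *
                y[id] * y[ig] * 0.0411;
  double Iup = VmaxUp / (1.0 + Kup * Kup / (Cai * Cai));
  double Ileak = (CaSR - Cai) * V_leak;
  double cai_buf = 1.0 + Buf_C * Kbuf_C / ((Cai + Kbuf_C) * (Cai + Kbuf_C));
  double casr_buf = 1.0 + Buf_SR * Kbuf_SR / ((CaSR + Kbuf_SR) * (CaSR + Kbuf_SR));
  double mem = (ICaL + IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * 1e-18 * F);

  y[iV] = v + dt * (-itot + istim);
  y[iCai] = Cai + dt * 1e-3 * (Irel + Ileak - Iup - mem) / cai_buf;
  if (y[iCai] < 1e-9) y[iCai] = 1e-9;
  y[iCaSR] = CaSR + dt * 1e-3 * (Vc / V_SR) * (Iup - Irel - Ileak) / casr_buf;
  if (y[iCaSR] < 1e-9) y[iCaSR] = 1e-9;
  y[iNai] = Nai + dt * 1e-3 * (-Cm * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) /
                               (F * Vc * 1e-18));
}

}  // namespace hipsc

const ModelDef& model_def_hipsc() {
  static const ModelDef def = {
      hipsc::N_STATE, hipsc::N_GATE, hipsc::N_SLOW, hipsc::NAMES,
      hipsc::initial_state, hipsc::rhs, hipsc::build_tables,
      hipsc::refresh_slow, hipsc::step};
  return def;
}

}  // namespace cardiomod
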