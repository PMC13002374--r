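#pragma once

#include <vector>
#include <cmath>
#include <map>
#include <string>
#include <stdexcept>

// Shared infrastructure for the two ionic models.
//
// State vector conventions (per element):
//   y[0]            membrane voltage, mV
//   y[1..n_gate]    Hodgkin-Huxley gates, dimensionless in [0,1]
//   y[n_gate+1..]   intracellular concentrations, mM
// All derivatives are per millisecond; currents are A/F (== mV/ms on Vm).
//
// Voltage-dependent gate kinetics and current coefficients are tabulated on
// a uniform Vm grid (one interleaved row per grid point, so each lookup
// touches two adjacent rows) and linearly interpolated; gates advance by
// Rush-Larsen (exponential relaxation towards the tabulated steady state).
// Slowly varying quantities (Nernst potentials, calcium-dependent gate
// targets) live in a per-element slow cache refreshed at a coarser cadence,
// with a cheap "light" refresh (calcium-dependent gate targets) and a
// periodic "heavy" refresh (Nernst potentials, slow rate factors).

namespace cardiomod {

constexpr int MODEL_HIPSC = 0;   // spontaneous hiPSC-CM model (Paci-type)
constexpr int MODEL_ATRIAL = 1;  // adult human atrial model (Courtemanche-type)

constexpr double TAB_VMIN = -150.0;
constexpr double TAB_VMAX = 100.0;
constexpr double TAB_DV = 0.05;

struct Tables {
  double dt = 0.0;    // reaction dt the rl factors were built for
  int n = 0;
  int stride = 0;     // doubles per v-row
  double vmin = TAB_VMIN, dv_inv = 1.0 / TAB_DV;
  std::vector<double> flat;    // n * stride, row-interleaved
  std::vector<double> consts;  // dt-dependent scalars (fixed-tau rl factors)
};

// Row-pair accessor for linear interpolation.
struct TabRow {
  const double* r0;
  const double* r1;
  double u;
  double operator()(int slot) const {
    return r0[slot] + u * (r1[slot] - r0[slot]);
  }
};

inline TabRow tab_row(const Tables& T, double v) {
  double x = (v - T.vmin) * T.dv_inv;
  if (x < 0.0) x = 0.0;
  double xmax = static_cast<double>(T.n) - 1.000001;
  if (x > xmax) x = xmax;
  int i = static_cast<int>(x);
  const double* r0 = T.flat.data() + static_cast<size_t>(i) * T.stride;
  return TabRow{r0, r0 + T.stride, x - i};
}

// Per-element slow cache.
struct SlowCache {
  int stride = 0;
  std::vector<double> buf;
  void resize(size_t n_el, int str) {
    stride = str;
    buf.assign(n_el * str, 0.0);
  }
  double* at(size_t el) { return buf.data() + el * stride; }
  const double* at(size_t el) const { return buf.data() + el * stride; }
};

struct ModelDef {
  int n_state;
  int n_gate;
  int n_slow;  // slots per element in the SlowCache
  const char* const* state_names;
  void (*initial_state)(double* y);
  // Full analytic right-hand side (used by the R-level ionic_rhs and the
  // adaptive-integrator oracle). Returns total ionic current (A/F).
  double (*rhs)(const double* y, double* dy, double s_na, double s_nak,
                double istim);
  void (*build_tables)(Tables& T, double dt);
  // Refresh the slow cache entry for element `el`; `heavy` additionally
  // recomputes Nernst potentials and slow rate factors.
  void (*refresh_slow)(const double* y, SlowCache& S, size_t el, double dt,
                       const Tables& T, bool heavy);
  // One Rush-Larsen/forward-Euler reaction step in place.
  void (*step)(double* y, double dt, const Tables& T, const SlowCache& S,
               size_t el, double s_na, double s_nak, double istim,
               long* clamped);
};

const ModelDef& model_def(int model_id);
const Tables& model_tables(int model_id, double dt);

inline double clamp_gate(double x, long* clamped) {
  if (x < 0.0) { ++*clamped; return 0.0; }
  if (x > 1.0) { ++*clamped; return 1.0; }
  return x;
}

}  // namespace cardiomod
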