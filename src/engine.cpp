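// Monodomain reaction-diffusion engine: Godunov operator splitting with
// Rush-Larsen/forward-Euler reaction sub-steps and an explicit 5-point
// Laplacian with harmonic-mean interface diffusivity and no-flux borders.

#include <Rcpp.h>
#include "models.h"

using namespace Rcpp;

namespace cardiomod {

const ModelDef& model_def_hipsc();
const ModelDef& model_def_atrial();

const ModelDef& model_def(int model_id) {
  if (model_id == MODEL_HIPSC) return model_def_hipsc();
  if (model_id == MODEL_ATRIAL) return model_def_atrial();
  throw std::invalid_argument("unknown model id");
}

const Tables& model_tables(int model_id, double dt) {
  static std::map<std::pair<int, long long>, Tables> cache;
  std::pair<int, long long> key(model_id,
                                static_cast<long long>(std::llround(dt * 1e9)));
  auto it = cache.find(key);
  if (it == cache.end()) {
    Tables T;
    model_def(model_id).build_tables(T, dt);
    it = cache.emplace(key, std::move(T)).first;
  }
  return it->second;
}

}  // namespace cardiomod

using namespace cardiomod;

// [[Rcpp::export(name = ".cm_model_info")]]
List cm_model_info(int model_id) {
  const ModelDef& def = model_def(model_id);
  CharacterVector nm(def.n_state);
  for (int i = 0; i < def.n_state; ++i) nm[i] = def.state_names[i];
  NumericVector y0(def.n_state);
  def.initial_state(REAL(y0));
  y0.names() = nm;
  return List::create(_["n_state"] = def.n_state, _["n_gate"] = def.n_gate,
                      _["state_names"] = nm, _["init"] = y0);
}

// [[Rcpp::export(name = ".cm_ionic_rhs")]]
NumericVector cm_ionic_rhs(int model_id, NumericVector y, double s_na,
                           double s_nak, double istim) {
  const ModelDef& def = model_def(model_id);
  if (y.size() != def.n_state)
    stop("state vector has %d entries; model expects %d", (int)y.size(),
         def.n_state);
  for (int i = 0; i < def.n_state; ++i) {
    if (!R_finite(y[i]))
      stop("non-finite state variable '%s'", def.state_names[i]);
  }
  NumericVector dy(def.n_state);
  double itot = def.rhs(REAL(y), REAL(dy), s_na, s_nak, istim);
  CharacterVector nm(def.n_state);
  for (int i = 0; i < def.n_state; ++i) nm[i] = def.state_names[i];
  dy.names() = nm;
  dy.attr("i_ion") = itot;
  return dy;
}

struct Train {
  double onset, cl, dur, amp;
  int n;
  std::vector<int> elems;
  bool on = false;
};

// [[Rcpp::export(name = ".cm_sim_run")]]
List cm_sim_run(int model_id, int nx, int ny, NumericVector D, double dx,
                NumericVector s_na, NumericVector s_nak, NumericMatrix state0,
                List trains, double duration, double dt_r, double dt_d,
                IntegerVector probes, double probe_every, double act_threshold,
                double refractory, int frame_every_macro, bool do_reaction,
                double blowup_mv, int refresh_every = 1, int heavy_every = 10,
                double hysteresis = 10.0) {
  const ModelDef& def = model_def(model_id);
  const R_xlen_t n_el = static_cast<R_xlen_t>(nx) * ny;
  if (D.size() != n_el || s_na.size() != n_el || s_nak.size() != n_el)
    stop("per-element fields must have nx*ny entries");
  if (state0.nrow() != def.n_state ||
      (state0.ncol() != n_el && state0.ncol() != 1))
    stop("state0 must be n_state x n_elements (or a single column)");
  if (dt_r <= 0 || dt_d <= 0) stop("time steps must be positive");
  int nsub = static_cast<int>(std::round(dt_d / dt_r));
  if (nsub < 1 || std::fabs(nsub * dt_r - dt_d) > 1e-9)
    stop("dt_diffusion must be a positive integer multiple of dt_reaction");
  double dmax = 0.0;
  for (R_xlen_t e = 0; e < n_el; ++e) if (D[e] > dmax) dmax = D[e];
  if (dmax > 0.0 && dt_d > dx * dx / (4.0 * dmax) * (1.0 + 1e-9))
    stop("CFL violation: dt_diffusion must be <= %g ms for this grid",
         dx * dx / (4.0 * dmax));

  const Tables& T = model_tables(model_id, dt_r);
  const int ns = def.n_state;

  // state copy (column per element)
  std::vector<double> Y(static_cast<size_t>(ns) * n_el);
  for (R_xlen_t e = 0; e < n_el; ++e) {
    const double* src = &state0(0, state0.ncol() == 1 ? 0 : e);
    std::copy(src, src + ns, Y.begin() + static_cast<size_t>(e) * ns);
  }

  // interface conductances (harmonic mean), x: el <-> el+1, y: el <-> el+nx
  std::vector<double> Gx(n_el, 0.0), Gy(n_el, 0.0);
  std::vector<char> active(n_el);
  for (R_xlen_t e = 0; e < n_el; ++e) active[e] = (D[e] >= 0.0);
  auto harm = [](double a, double b) {
    return (a > 0.0 && b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
  };
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t e = ix + static_cast<R_xlen_t>(iy) * nx;
      if (ix < nx - 1) Gx[e] = harm(D[e], D[e + 1]);
      if (iy < ny - 1) Gy[e] = harm(D[e], D[e + nx]);
    }

  std::vector<Train> tr;
  for (R_xlen_t i = 0; i < trains.size(); ++i) {
    List t = trains[i];
    Train x;
    x.onset = as<double>(t["onset_ms"]);
    x.cl = as<double>(t["cycle_length_ms"]);
    x.n = as<int>(t["n_pulses"]);
    x.dur = as<double>(t["pulse_ms"]);
    x.amp = as<double>(t["amplitude"]);
    IntegerVector el = t["elements"];
    x.elems.assign(el.begin(), el.end());
    for (int e : x.elems)
      if (e < 0 || e >= n_el) stop("stimulus element index out of range");
    tr.push_back(x);
  }

  SlowCache S;
  S.resize(n_el, def.n_slow);

  long n_macro = static_cast<long>(std::round(duration / dt_d));
  int probe_k = probe_every > 0
      ? std::max(1, static_cast<int>(std::round(probe_every / dt_d))) : 0;
  long n_rec = (probes.size() > 0 && probe_k > 0) ? n_macro / probe_k + 1 : 0;
  NumericMatrix probe_v(n_rec, probes.size());
  NumericVector probe_t(n_rec);
  long n_frames = frame_every_macro > 0 ? n_macro / frame_every_macro + 1 : 0;
  NumericMatrix frames(n_frames > 0 ? n_el : 0, n_frames);
  NumericVector frame_t(n_frames);

  std::vector<std::vector<double>> acts(n_el);
  std::vector<double> last_act(n_el, -1e18);
  std::vector<double> istim(n_el, 0.0), vbuf(n_el);
  // Schmitt-trigger arming: an upward threshold crossing only registers
  // after the voltage has been at least `hysteresis` mV below threshold,
  // suppressing double counts from ripples at the crossing level
  const double thr_low = act_threshold - hysteresis;
  std::vector<char> armed(n_el);
  for (R_xlen_t e = 0; e < n_el; ++e)
    armed[e] = Y[static_cast<size_t>(e) * ns] < thr_low;

  long clamped = 0;
  bool blowup = false;
  double blowup_time = NA_REAL;
  long rec_i = 0, frame_i = 0;

  auto record_probes = [&](double t) {
    if (rec_i >= n_rec) return;
    for (R_xlen_t p = 0; p < probes.size(); ++p)
      probe_v(rec_i, p) = Y[static_cast<size_t>(probes[p]) * ns];
    probe_t[rec_i] = t;
    ++rec_i;
  };
  auto record_frame = [&](double t) {
    if (frame_i >= n_frames) return;
    for (R_xlen_t e = 0; e < n_el; ++e)
      frames(e, frame_i) = Y[static_cast<size_t>(e) * ns];
    frame_t[frame_i] = t;
    ++frame_i;
  };
  auto note_crossing = [&](R_xlen_t e, double v0, double v1, double t0,
                           double step) {
    if (armed[e] && v0 < act_threshold && v1 >= act_threshold) {
      double tc = t0 + step * (act_threshold - v0) / (v1 - v0);
      if (tc - last_act[e] >= refractory) {
        acts[e].push_back(tc);
        last_act[e] = tc;
      }
      armed[e] = false;
    } else if (!armed[e] && v1 < thr_low) {
      armed[e] = true;
    }
  };

  if (n_rec > 0) record_probes(0.0);
  if (n_frames > 0) record_frame(0.0);

  const double inv_dx2 = 1.0 / (dx * dx);
  int k_diff = 1;
  if (dmax > 0.0) {
    double smooth_dt = dx * dx / (8.0 * dmax);
    k_diff = std::max(1, static_cast<int>(std::ceil(dt_d / smooth_dt - 1e-9)));
  }
  if (refresh_every < 1) refresh_every = 1;
  if (heavy_every < 1) heavy_every = 1;
  long refresh_count = 0;
  for (long macro = 0; macro < n_macro && !blowup; ++macro) {
    double t0 = macro * dt_d;
    if (do_reaction) {
      if (macro % refresh_every == 0) {
        bool heavy = (refresh_count % heavy_every == 0);
        ++refresh_count;
        for (R_xlen_t e = 0; e < n_el; ++e)
          if (active[e])
            def.refresh_slow(&Y[static_cast<size_t>(e) * ns], S, e, dt_r, T,
                             heavy);
      }
      for (int sub = 0; sub < nsub; ++sub) {
        double t = t0 + sub * dt_r;
        for (auto& x : tr) {
          bool on = false;
          double ph = t - x.onset;
          if (ph >= 0.0 && x.n > 0) {
            long kk = static_cast<long>(ph / x.cl);
            if (kk < x.n && (ph - kk * x.cl) < x.dur) on = true;
          }
          if (on != x.on) {
            double dlt = on ? x.amp : -x.amp;
            for (int e : x.elems) istim[e] += dlt;
            x.on = on;
          }
        }
        for (R_xlen_t e = 0; e < n_el; ++e) {
          if (!active[e]) continue;
          double* y = &Y[static_cast<size_t>(e) * ns];
          double v0 = y[0];
          def.step(y, dt_r, T, S, e, s_na[e], s_nak[e], istim[e], &clamped);
          note_crossing(e, v0, y[0], t, dt_r);
        }
      }
    }
    // diffusion over the splitting interval: the explicit update is applied
    // in k_diff sub-sweeps so each stays in the smooth (non-oscillatory)
    // regime D*dt/dx^2 <= 1/8; crossings are interpolated over the full
    // interval
    double t_end = t0 + dt_d;
    {
      double dt_sub = dt_d / k_diff;
      for (int sweep = 0; sweep < k_diff; ++sweep) {
        for (R_xlen_t e = 0; e < n_el; ++e)
          vbuf[e] = Y[static_cast<size_t>(e) * ns];
        for (int iy = 0; iy < ny; ++iy) {
          for (int ix = 0; ix < nx; ++ix) {
            R_xlen_t e = ix + static_cast<R_xlen_t>(iy) * nx;
            double acc = 0.0;
            if (ix > 0 && Gx[e - 1] > 0.0) acc += Gx[e - 1] * (vbuf[e - 1] - vbuf[e]);
            if (ix < nx - 1 && Gx[e] > 0.0) acc += Gx[e] * (vbuf[e + 1] - vbuf[e]);
            if (iy > 0 && Gy[e - nx] > 0.0) acc += Gy[e - nx] * (vbuf[e - nx] - vbuf[e]);
            if (iy < ny - 1 && Gy[e] > 0.0) acc += Gy[e] * (vbuf[e + nx] - vbuf[e]);
            if (acc != 0.0) {
              double vnew = vbuf[e] + dt_sub * inv_dx2 * acc;
              Y[static_cast<size_t>(e) * ns] = vnew;
              note_crossing(e, vbuf[e], vnew, t0 + sweep * dt_sub, dt_sub);
            }
          }
        }
      }
      for (R_xlen_t e = 0; e < n_el; ++e) {
        double vcur = Y[static_cast<size_t>(e) * ns];
        if (!R_finite(vcur) || std::fabs(vcur) > blowup_mv) {
          blowup = true;
          blowup_time = t_end;
        }
      }
    }
    if (n_rec > 0 && (macro + 1) % probe_k == 0) record_probes(t_end);
    if (n_frames > 0 && (macro + 1) % frame_every_macro == 0) record_frame(t_end);
    if ((macro & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List acts_r(n_el);
  for (R_xlen_t e = 0; e < n_el; ++e) acts_r[e] = wrap(acts[e]);
  NumericMatrix final_state(ns, n_el);
  for (R_xlen_t e = 0; e < n_el; ++e)
    std::copy(Y.begin() + static_cast<size_t>(e) * ns,
              Y.begin() + static_cast<size_t>(e + 1) * ns,
              &final_state(0, e));
  CharacterVector nm(ns);
  for (int i = 0; i < ns; ++i) nm[i] = def.state_names[i];
  rownames(final_state) = nm;

  return List::create(
      _["activations"] = acts_r, _["probe_t"] = probe_t,
      _["probe_v"] = probe_v, _["frames"] = frames, _["frame_t"] = frame_t,
      _["state"] = final_state, _["gate_clamp_count"] = (double)clamped,
      _["blowup"] = blowup, _["blowup_time"] = blowup_time);
}
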