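# Single-cell electrophysiology: model registry, state handling, the ionic
# right-hand side, and zero-dimensional (single cell) simulation.

.model_ids <- c(hipsc = 0L, atrial = 1L)

# Per-model numerical and protocol defaults. Diffusivities are the package's
# calibrated control values (see calibrate_conductivity); conduction-velocity
# targets are the control calibration targets in cm/s.
.model_defaults <- list(
  hipsc = list(
    dt_reaction = 0.02,       # ms, single-cell default (dt-convergence tested)
    tissue_dt_cap = 0.05,     # ms, upper bound for tissue runs; the CFL
                              # bound at calibrated conductivity binds first
    cable_dt = 0.025,         # ms, calibration cables
    dt_diffusion = 0.1,       # ms
    refractory = 100,         # ms debounce for activation detection
    threshold_mv = 0,         # activation registration threshold
    stim_amplitude = 30,      # A/F
    stim_ms = 3,
    cv_target_cm_s = 45,
    diffusivity = 4.157e-3,   # cm^2/ms; calibrate_conductivity() control value
    settle_ms = 10000,
    dx_um = 250
  ),
  atrial = list(
    dt_reaction = 0.02,
    tissue_dt_cap = 0.02,
    cable_dt = 0.02,
    dt_diffusion = 0.04,
    refractory = 50,
    threshold_mv = -60,       # propagating atrial upstrokes overshoot only
                              # a few mV at desk-scale dx; the upstroke
                              # foot is crossed briskly both ways (the plateau lingers near -40)
    stim_amplitude = 40,      # pA/pF
    stim_ms = 2,
    cv_target_cm_s = 80,
    diffusivity = 2.492e-3,   # cm^2/ms; calibrate_conductivity() control value
    settle_ms = 1000,
    dx_um = 250
  )
)

.model_id <- function(model) {
  model <- match.arg(model, names(.model_ids))
  .model_ids[[model]]
}

.model_default <- function(model, what) {
  model <- match.arg(model, names(.model_ids))
  .model_defaults[[model]][[what]]
}

#' Available ionic models
#'
#' @return Character vector of model identifiers: `"hipsc"` (spontaneously
#'   beating hiPSC-CM model, Paci et al. 2013 ventricular-like variant) and
#'   `"atrial"` (adult human atrial model, Courtemanche, Ramirez & Nattel
#'   1998).
#' @export
cell_models <- function() names(.model_ids)

#' Published initial state of an ionic model
#'
#' @param model `"hipsc"` or `"atrial"`.
#' @return Named numeric vector: membrane voltage `v` (mV), gating variables
#'   (dimensionless), and intracellular concentrations (mM).
#' @export
cell_initial_state <- function(model = c("hipsc", "atrial")) {
  info <- .cm_model_info(.model_id(match.arg(model)))
  info$init
}

#' Multiplicative current scalers
#'
#' Control is `(1, 1)`; inflammatory remodeling downregulates by setting a
#' scaler below 1 (e.g. 0.5 for a 50% reduction). Conductivity scaling is a
#' tissue property and lives on the grid, not here.
#'
#' @param s_na Multiplier on the fast sodium current I_Na, in `[0, 2]`.
#' @param s_nak Multiplier on the Na+/K+ pump current I_NaK, in `[0, 2]`.
#' @return An object of class `current_scalers`.
#' @export
current_scalers <- function(s_na = 1, s_nak = 1) {
  stopifnot(is.numeric(s_na), length(s_na) == 1L, is.finite(s_na),
            is.numeric(s_nak), length(s_nak) == 1L, is.finite(s_nak))
  if (s_na < 0 || s_na > 2 || s_nak < 0 || s_nak > 2)
    stop("current scalers must lie in [0, 2] (1 = control)")
  structure(list(s_na = s_na, s_nak = s_nak), class = "current_scalers")
}

.as_scalers <- function(scalers) {
  if (is.null(scalers)) return(current_scalers())
  if (inherits(scalers, "current_scalers")) return(scalers)
  if (is.numeric(scalers) && !is.null(names(scalers)))
    return(current_scalers(s_na = unname(scalers[["s_na"]]),
                           s_nak = unname(scalers[["s_nak"]])))
  stop("scalers must be a current_scalers() object")
}

#' @export
print.current_scalers <- function(x, ...) {
  cat(sprintf("current scalers: s_na = %g, s_nak = %g\n", x$s_na, x$s_nak))
  invisible(x)
}

#' Ionic model right-hand side
#'
#' Evaluates the full time derivative of an ionic model state and the total
#' ionic current. The I_Na term in the total current is exactly
#' `s_na * I_Na` and the I_NaK term exactly `s_nak * I_NaK`; all other
#' currents are unmodified.
#'
#' @param state Named numeric state vector (see [cell_initial_state()]).
#' @param model `"hipsc"` or `"atrial"`.
#' @param scalers A [current_scalers()] object.
#' @param i_stim External stimulus current (A/F, depolarizing positive).
#' @return List with `dstate` (derivative per ms) and `i_ion` (total ionic
#'   current, A/F).
#' @export
ionic_rhs <- function(state, model = c("hipsc", "atrial"), scalers = NULL,
                      i_stim = 0) {
  model <- match.arg(model)
  sc <- .as_scalers(scalers)
  dy <- .cm_ionic_rhs(.model_id(model), as.numeric(state), sc$s_na, sc$s_nak,
                      i_stim)
  list(dstate = stats::setNames(as.numeric(dy), names(dy)),
       i_ion = attr(dy, "i_ion"))
}

# Session cache for settled states.
.cm_cache <- new.env(parent = emptyenv())

#' Settled single-cell state
#'
#' Pre-runs a single cell to settle onto its attractor before any recorded
#' experiment. For the spontaneous hiPSC model the snapshot is taken at the
#' maximum diastolic potential (the most excitable phase, farthest from the
#' next spontaneous upstroke); the quiescent atrial model simply relaxes at
#' rest.
#'
#' @param model `"hipsc"` or `"atrial"`.
#' @param settle_ms Settling duration (ms); default 10 s for the hiPSC
#'   model, 1 s for the atrial model.
#' @param dt Reaction time step (ms); model default if `NULL`.
#' @param scalers Optional [current_scalers()] applied during settling.
#' @return Named numeric state vector.
#' @export
settled_state <- function(model = c("hipsc", "atrial"), settle_ms = NULL,
                          dt = NULL, scalers = NULL) {
  model <- match.arg(model)
  if (is.null(settle_ms)) settle_ms <- .model_default(model, "settle_ms")
  if (is.null(dt)) dt <- .model_default(model, "dt_reaction")
  sc <- .as_scalers(scalers)
  key <- paste(model, settle_ms, dt, sc$s_na, sc$s_nak, sep = "|")
  hit <- .cm_cache[[key]]
  if (!is.null(hit)) return(hit)

  if (model == "atrial") {
    res <- run_single_cell(model, scalers = sc, duration_ms = settle_ms,
                           dt = dt, output_dt = settle_ms)
    out <- attr(res, "state")
  } else {
    # settle, then land on the maximum diastolic potential
    scan_ms <- 3000
    res <- run_single_cell(model, scalers = sc,
                           duration_ms = settle_ms + scan_ms, dt = dt,
                           output_dt = 1)
    tr <- res[res$time_ms >= settle_ms, ]
    t_mdp <- tr$time_ms[which.min(tr$v_m)]
    res2 <- run_single_cell(model, scalers = sc, duration_ms = t_mdp,
                            dt = dt, output_dt = t_mdp)
    out <- attr(res2, "state")
  }
  .cm_cache[[key]] <- out
  out
}

#' Simulate a single cell
#'
#' Integrates one ionic model cell with Rush-Larsen gate updates and forward
#' Euler for voltage and concentrations (the same reaction integrator used
#' inside the tissue solver).
#'
#' @param model `"hipsc"` or `"atrial"`.
#' @param scalers A [current_scalers()] object (control if `NULL`).
#' @param protocol A [stimulus_protocol()]; `NULL` for no stimulus. Trains
#'   target the single cell regardless of their region label.
#' @param duration_ms Simulated duration (ms); `duration_ms = 0` returns an
#'   empty trace with the state unchanged. Defaults to the protocol duration.
#' @param dt Reaction time step (ms); model default if `NULL`.
#' @param output_dt Trace sampling interval (ms).
#' @param init Initial state vector; published initial conditions if `NULL`.
#' @return A `voltage_trace` data frame with columns `time_ms`, `v_m` (mV)
#'   and attributes `state` (final state), `activations` (upward 0 mV
#'   crossing times) and `gate_clamp_count`.
#' @export
run_single_cell <- function(model = c("hipsc", "atrial"), scalers = NULL,
                            protocol = NULL, duration_ms = NULL, dt = NULL,
                            output_dt = 1, init = NULL) {
  model <- match.arg(model)
  sc <- .as_scalers(scalers)
  if (is.null(dt)) dt <- .model_default(model, "dt_reaction")
  if (is.null(duration_ms)) {
    if (is.null(protocol)) stop("duration_ms is required without a protocol")
    duration_ms <- protocol$duration_ms
  }
  stopifnot(duration_ms >= 0, dt > 0)
  if (is.null(init)) init <- cell_initial_state(model)
  init <- as.numeric(init)

  if (duration_ms == 0) {
    out <- data.frame(time_ms = numeric(0), v_m = numeric(0))
    class(out) <- c("voltage_trace", "data.frame")
    attr(out, "state") <- init
    attr(out, "activations") <- numeric(0)
    attr(out, "gate_clamp_count") <- 0
    return(out)
  }

  trains <- .resolve_trains(protocol, regions = list(), n_el = 1L,
                            default_amp = .model_default(model, "stim_amplitude"))
  # macro step: diffusion is inert (D = 0) but sets the slow-cache cadence
  dt_macro <- dt * max(1, floor(0.1 / dt + 1e-9))
  res <- .cm_sim_run(.model_id(model), 1L, 1L, 0.0, 1.0,
                     sc$s_na, sc$s_nak, matrix(init, ncol = 1),
                     trains, duration_ms, dt, dt_macro,
                     0L, output_dt, 0.0,
                     .model_default(model, "refractory"),
                     0L, TRUE, 200.0)
  if (isTRUE(res$blowup))
    stop(sprintf("integration blow-up (|V_m| > 200 mV) at t = %.3f ms",
                 res$blowup_time))
  out <- data.frame(time_ms = res$probe_t, v_m = res$probe_v[, 1])
  class(out) <- c("voltage_trace", "data.frame")
  st <- res$state[, 1]
  names(st) <- rownames(res$state)
  attr(out, "state") <- st
  attr(out, "activations") <- res$activations[[1]]
  attr(out, "gate_clamp_count") <- res$gate_clamp_count
  out
}
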