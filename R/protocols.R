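# Experiment drivers: stimulus protocols (spontaneous, pacing, stress
# pacing) and conductivity calibration against a conduction-velocity target.

#' Define one pacing train
#'
#' @param onset_ms Time of the first pulse (ms).
#' @param cycle_length_ms Interval between pulse onsets (ms).
#' @param n_pulses Number of pulses.
#' @param pulse_ms Pulse duration (ms); must be shorter than the cycle length.
#' @param amplitude Pulse amplitude (A/F, depolarizing positive); the model
#'   default is used when `NULL`.
#' @param region Name of the grid region the train targets (resolved when
#'   the protocol is run; single-cell runs ignore it).
#' @return A `pacing_train` object.
#' @export
pacing_train <- function(onset_ms, cycle_length_ms, n_pulses, pulse_ms = 2,
                         amplitude = NULL, region = "pacing_site") {
  stopifnot(onset_ms >= 0, n_pulses >= 1, pulse_ms > 0)
  if (cycle_length_ms <= pulse_ms)
    stop("cycle length must exceed the pulse duration")
  structure(list(onset_ms = onset_ms, cycle_length_ms = cycle_length_ms,
                 n_pulses = as.integer(n_pulses), pulse_ms = pulse_ms,
                 amplitude = amplitude, region = region),
            class = "pacing_train")
}

#' Assemble a stimulus protocol
#'
#' @param ... Zero or more [pacing_train()] objects (none = spontaneous).
#' @param duration_ms Total simulated duration (ms).
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(..., duration_ms) {
  trains <- list(...)
  if (length(trains) == 1L && is.list(trains[[1]]) &&
      !inherits(trains[[1]], "pacing_train"))
    trains <- trains[[1]]
  for (tr in trains)
    if (!inherits(tr, "pacing_train")) stop("trains must be pacing_train objects")
  stopifnot(is.numeric(duration_ms), duration_ms > 0)
  # reject overlapping pulses within a shared target region
  by_region <- split(trains, vapply(trains, `[[`, "", "region"))
  for (grp in by_region) {
    win <- do.call(rbind, lapply(grp, function(tr) {
      k <- seq_len(tr$n_pulses) - 1
      cbind(tr$onset_ms + k * tr$cycle_length_ms,
            tr$onset_ms + k * tr$cycle_length_ms + tr$pulse_ms)
    }))
    if (!is.null(win) && nrow(win) > 1) {
      o <- order(win[, 1])
      if (any(win[o, 1][-1] < win[o, 2][-nrow(win)]))
        stop("overlapping stimulus pulses within one region")
    }
  }
  structure(list(trains = trains, duration_ms = duration_ms),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus protocol: %d train(s), duration %g ms\n",
              length(x$trains), x$duration_ms))
  for (tr in x$trains)
    cat(sprintf("  onset %g ms | CL %g ms | %d pulses | %g ms @ %s | region %s\n",
                tr$onset_ms, tr$cycle_length_ms, tr$n_pulses, tr$pulse_ms,
                ifelse(is.null(tr$amplitude), NA, tr$amplitude), tr$region))
  invisible(x)
}

#' Spontaneous-activity protocol
#'
#' An empty stimulus train: the tissue is left to its intrinsic automaticity.
#' Default duration 50 s, the standard recording length for spontaneous
#' hiPSC-CM tissue activity.
#'
#' @param duration_ms Simulated duration (ms), default 50000.
#' @return A `stimulus_protocol` with zero pulses.
#' @export
spontaneous_protocol <- function(duration_ms = 50000) {
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L || duration_ms <= 0)
    stop("duration_ms must be a positive number")
  stimulus_protocol(duration_ms = duration_ms)
}

#' Sinus-plus-tachycardia stress-pacing protocol
#'
#' Sinus rhythm for `sinus_beats` beats at `sinus_bpm`, then a stress phase
#' at `stress_bpm` for `stress_beats` beats, starting one stress cycle after
#' the last sinus pulse. Defaults: 10 beats at 85 bpm (cycle length 700 ms)
#' followed by 5 beats at 190 bpm (cycle length 310 ms).
#'
#' @param onset_ms Time of the first sinus pulse (ms).
#' @param sinus_bpm,sinus_beats Sinus phase rate (bpm) and beat count.
#' @param stress_bpm,stress_beats Stress phase rate (bpm) and beat count.
#' @param pulse_ms Pulse duration (ms).
#' @param amplitude Pulse amplitude (model default when `NULL`).
#' @param region Target region (default the sinus-node pacing site).
#' @param tail_ms Quiescent observation window appended after the last
#'   pulse (ms); used to detect self-sustained activity.
#' @return A `stimulus_protocol` with two trains.
#' @export
stress_pacing_protocol <- function(onset_ms = 50, sinus_bpm = 85,
                                   sinus_beats = 10, stress_bpm = 190,
                                   stress_beats = 5, pulse_ms = 2,
                                   amplitude = NULL, region = "pacing_site",
                                   tail_ms = 2500) {
  # conventional rounded cycle lengths: 85 bpm -> 700 ms, 190 bpm -> 310 ms
  cl1 <- if (sinus_bpm == 85) 700 else 60000 / sinus_bpm
  cl2 <- if (stress_bpm == 190) 310 else 60000 / stress_bpm
  t1 <- pacing_train(onset_ms, cl1, sinus_beats, pulse_ms, amplitude, region)
  stress_onset <- onset_ms + (sinus_beats - 1) * cl1 + cl2
  t2 <- pacing_train(stress_onset, cl2, stress_beats, pulse_ms, amplitude,
                     region)
  last_pulse <- stress_onset + (stress_beats - 1) * cl2
  stimulus_protocol(t1, t2, duration_ms = last_pulse + pulse_ms + tail_ms)
}

#' Last stimulus time of a protocol
#'
#' @param protocol A `stimulus_protocol`.
#' @return Onset time (ms) of the final pulse, or `-Inf` if unpaced.
#' @export
last_stimulus_time <- function(protocol) {
  if (length(protocol$trains) == 0) return(-Inf)
  max(vapply(protocol$trains, function(tr)
    tr$onset_ms + (tr$n_pulses - 1) * tr$cycle_length_ms, 0))
}

# Resolve trains against a grid's named regions into the flat 0-based
# element lists the solver consumes.
.resolve_trains <- function(protocol, regions, n_el, default_amp) {
  if (is.null(protocol) || length(protocol$trains) == 0) return(list())
  lapply(protocol$trains, function(tr) {
    amp <- if (is.null(tr$amplitude)) default_amp else tr$amplitude
    if (n_el == 1L) {
      el <- 0L
    } else {
      if (is.null(regions[[tr$region]]))
        stop(sprintf("protocol targets unknown region '%s'", tr$region))
      el <- as.integer(regions[[tr$region]] - 1L)
    }
    list(onset_ms = tr$onset_ms, cycle_length_ms = tr$cycle_length_ms,
         n_pulses = tr$n_pulses, pulse_ms = tr$pulse_ms, amplitude = amp,
         elements = el)
  })
}

#' Measure planar conduction velocity on a cable
#'
#' Builds a 1D cable (single-element-wide strip), initializes every element
#' from the settled single-cell state, triggers one wave by edge
#' stimulation, and measures conduction velocity from the activation-time
#' difference between probes at 25% and 75% of cable length. For the
#' spontaneous hiPSC model the settled state is snapshot at maximum
#' diastolic potential, so the triggered wave completes well before the
#' next spontaneous upstroke; a spontaneous activation during the
#' measurement window invalidates the run.
#'
#' @param model `"hipsc"` or `"atrial"`.
#' @param diffusivity Monodomain diffusivity (cm^2/ms).
#' @param n_elements Cable length in elements (default 200 = 5 cm at 250 um).
#' @param dx_um Element edge length (micrometers).
#' @param dt Reaction time step (ms); model default if `NULL`.
#' @return List with `cv_cm_s` (NA if the wave failed to propagate),
#'   `t25_ms`, `t75_ms` and `valid`.
#' @export
measure_cable_cv <- function(model = c("hipsc", "atrial"), diffusivity,
                             n_elements = 200, dx_um = 250, dt = NULL) {
  model <- match.arg(model)
  if (is.null(dt)) dt <- .model_default(model, "cable_dt")
  stopifnot(diffusivity > 0, n_elements >= 16)
  dx_cm <- dx_um * 1e-4
  n <- as.integer(n_elements)
  init <- settled_state(model, dt = dt)
  # CFL-safe macro step (integer multiple of dt)
  dt_d <- dt * max(1, floor(dx_cm^2 / (4 * diffusivity) / dt))
  dt_d <- min(dt_d, dt * max(1, floor(0.1 / dt + 1e-9)))
  if (dx_cm^2 / (4 * diffusivity) < dt)
    stop(sprintf(
      "diffusivity %g too large for dt %g at dx %g um (CFL limit %g ms)",
      diffusivity, dt, dx_um, dx_cm^2 / (4 * diffusivity)))

  stim_t <- 5
  cable_cm <- n * dx_cm
  cv_floor <- 0.2 * .model_default(model, "cv_target_cm_s") / 1000  # cm/ms
  t_max <- stim_t + 0.8 * cable_cm / cv_floor
  t_max <- ceiling(t_max / dt_d) * dt_d

  # checkpoints along the cable; CV is read between the 25% and 75% probes,
  # the outer checkpoints guard against spontaneous foci (activation order
  # must be monotone away from the stimulated edge)
  chk <- unique(pmax(1L, pmin(n, as.integer(round(c(0.10, 0.25, 0.50, 0.75,
                                                    0.90) * n)))))
  # stimulate a fixed physical length (1 mm) so wave launch does not depend
  # on the element size
  n_stim <- max(3L, as.integer(round(0.1 / dx_cm)))
  trains <- list(list(onset_ms = stim_t, cycle_length_ms = t_max + 1,
                      n_pulses = 1L,
                      pulse_ms = .model_default(model, "stim_ms"),
                      amplitude = .model_default(model, "stim_amplitude"),
                      elements = 0:(n_stim - 1L)))
  ra <- .refresh_args(dt_d)
  res <- .cm_sim_run(.model_id(model), n, 1L, rep(diffusivity, n), dx_cm,
                     rep(1, n), rep(1, n), matrix(init, ncol = 1),
                     trains, t_max, dt, dt_d,
                     chk - 1L, 0,
                     0.0, .model_default(model, "refractory"),
                     0L, TRUE, 200.0,
                     ra$refresh_every, ra$heavy_every)
  firsts <- vapply(res$activations[chk], function(a)
    if (length(a) >= 1) a[1] else NA_real_, 0)
  bad <- anyNA(firsts) || isTRUE(res$blowup) ||
    is.unsorted(firsts, strictly = TRUE) || firsts[1] <= stim_t
  p25 <- as.integer(round(0.25 * n)); p75 <- as.integer(round(0.75 * n))
  t25 <- firsts[match(p25, chk)]; t75 <- firsts[match(p75, chk)]
  if (bad)
    return(list(cv_cm_s = NA_real_, t25_ms = t25, t75_ms = t75,
                valid = FALSE))
  dist_cm <- (p75 - p25) * dx_cm
  list(cv_cm_s = 1000 * dist_cm / (t75 - t25), t25_ms = t25, t75_ms = t75,
       valid = TRUE)
}

#' Calibrate tissue diffusivity to a conduction-velocity target
#'
#' Bisection on log-diffusivity, bracketed using the square-root relation
#' between conduction velocity and diffusivity (cable theory), until the
#' independently measured planar conduction velocity on a >= 4 cm cable is
#' within tolerance of the target. Default targets: 45 cm/s for control
#' hiPSC-CM tissue and 0.8 m/s (80 cm/s) for the adult atrial body.
#'
#' @param model `"hipsc"` or `"atrial"`.
#' @param target_cv_cm_s Target conduction velocity (cm/s); the model's
#'   control target when `NULL`.
#' @param tolerance Relative tolerance on the measured velocity (default 2%).
#' @param n_elements,dx_um,dt Passed to [measure_cable_cv()].
#' @param max_iter Maximum bisection iterations.
#' @return A `cv_calibration` list: `diffusivity` (cm^2/ms), `cv_cm_s`
#'   (measured at the returned diffusivity), `target_cv_cm_s`, `iterations`,
#'   `history` (data frame of trial diffusivities and velocities).
#' @export
calibrate_conductivity <- function(model = c("hipsc", "atrial"),
                                   target_cv_cm_s = NULL, tolerance = 0.02,
                                   n_elements = 200, dx_um = 250, dt = NULL,
                                   max_iter = 40) {
  model <- match.arg(model)
  if (is.null(target_cv_cm_s))
    target_cv_cm_s <- .model_default(model, "cv_target_cm_s")
  stopifnot(target_cv_cm_s > 0, tolerance > 0)
  if (is.null(dt)) dt <- .model_default(model, "cable_dt")
  dx_cm <- dx_um * 1e-4
  d_cap <- 0.999 * dx_cm^2 / (4 * dt)  # CFL ceiling at this dx, dt

  history <- data.frame(diffusivity = numeric(0), cv_cm_s = numeric(0))
  measure <- function(d) {
    m <- measure_cable_cv(model, d, n_elements, dx_um, dt)
    cv <- if (isTRUE(m$valid)) m$cv_cm_s else 0  # failed conduction: too slow
    history[nrow(history) + 1L, ] <<- c(d, cv)
    cv
  }

  d0 <- min(.model_default(model, "diffusivity"), d_cap)
  cv0 <- measure(d0)
  if (cv0 <= 0) {
    d0 <- min(d0 * 8, d_cap)
    cv0 <- measure(d0)
    if (cv0 <= 0) stop("calibration cable does not conduct; cannot calibrate")
  }
  # bracket via the sqrt(D) law (capped at the CFL ceiling), then expand
  d_guess <- d0 * (target_cv_cm_s / cv0)^2
  hi <- min(d_guess * 4, d_cap)
  lo <- min(d_guess / 4, hi / 4)
  cv_lo <- measure(lo)
  cv_hi <- measure(hi)
  expand <- 0
  while (cv_lo > target_cv_cm_s && expand < 8) {
    hi <- lo; cv_hi <- cv_lo; lo <- lo / 4; cv_lo <- measure(lo); expand <- expand + 1
  }
  while (cv_hi < target_cv_cm_s && hi < d_cap && expand < 8) {
    lo <- hi; cv_lo <- cv_hi; hi <- min(hi * 4, d_cap); cv_hi <- measure(hi)
    expand <- expand + 1
  }
  if (cv_lo > target_cv_cm_s || cv_hi < target_cv_cm_s)
    stop(sprintf(
      "target CV %g cm/s is outside the achievable range [%g, %g] cm/s",
      target_cv_cm_s, min(cv_lo, cv_hi), max(cv_lo, cv_hi)))

  best_d <- NA_real_; best_cv <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- exp((log(lo) + log(hi)) / 2)
    cv <- measure(mid)
    if (is.na(best_cv) ||
        abs(cv - target_cv_cm_s) < abs(best_cv - target_cv_cm_s)) {
      best_d <- mid; best_cv <- cv
    }
    if (abs(cv - target_cv_cm_s) <= 0.25 * tolerance * target_cv_cm_s) break
    if (cv < target_cv_cm_s) lo <- mid else hi <- mid
  }
  if (abs(best_cv - target_cv_cm_s) > tolerance * target_cv_cm_s)
    stop(sprintf(
      "calibration did not reach %g cm/s within %.1f%% (best %g cm/s)",
      target_cv_cm_s, 100 * tolerance, best_cv))
  structure(list(diffusivity = best_d, cv_cm_s = best_cv,
                 target_cv_cm_s = target_cv_cm_s, tolerance = tolerance,
                 iterations = nrow(history), history = history,
                 model = model, n_elements = n_elements, dx_um = dx_um,
                 dt = dt),
            class = "cv_calibration")
}

#' @export
print.cv_calibration <- function(x, ...) {
  cat(sprintf(
    "conductivity calibration (%s): D = %.5g cm^2/ms -> CV %.2f cm/s (target %g, %d runs)\n",
    x$model, x$diffusivity, x$cv_cm_s, x$target_cv_cm_s, x$iterations))
  invisible(x)
}
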