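# Seeded synthetic readout generators with known ground truth: beat-event
# series (stand-ins for contraction-video / calcium-peak / electrode beat
# detections), analytic activation-time maps, stylized action potential
# traces, and von Mises conduction-direction fields. Every generator is
# deterministic under a fixed seed and carries its generating parameters in
# a `ground_truth` attribute.

.with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for synthetic generators")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic beat-event series
#'
#' Inter-event intervals are i.i.d. gamma with the requested mean and
#' coefficient of variation (shape `1/cv^2`, positive support, no
#' truncation bias); `cv_pct = 0` gives an exactly periodic series. Event
#' times are the cumulative sums.
#'
#' @param n Number of events (>= 3).
#' @param mean_rate_bpm Mean beat rate (min^-1).
#' @param cv_pct Coefficient of variation of the intervals, in percent.
#' @param seed RNG seed (mandatory).
#' @param t0_ms Time of the first event.
#' @return A [beat_series()] with a `ground_truth` attribute.
#' @export
gen_beat_series <- function(n, mean_rate_bpm = 60, cv_pct = 0, seed,
                            t0_ms = 0) {
  stopifnot(n >= 3, mean_rate_bpm > 0)
  if (cv_pct < 0) stop("cv_pct must be non-negative")
  mu <- 60000 / mean_rate_bpm
  cv <- cv_pct / 100
  iv <- .with_seed(seed, {
    if (cv == 0) rep(mu, n - 1)
    else stats::rgamma(n - 1, shape = 1 / cv^2, scale = mu * cv^2)
  })
  out <- beat_series(t0_ms + cumsum(c(0, iv)))
  attr(out, "ground_truth") <- list(kind = "beat_series", n = n,
                                    mean_rate_bpm = mean_rate_bpm,
                                    cv_pct = cv_pct, seed = seed)
  out
}

#' Generate a synthetic activation-time map
#'
#' Analytic activation surfaces per beat at a stated wave speed:
#' `"planar"` (wave along +x), `"focal"` (radial from a point source),
#' `"collision"` (two planar sources from opposite edges), or `"reentry"`
#' (planar paced beats followed by a rotor-like, phase-over-angle periodic
#' re-activation, for testing sustained-activity detection). Optional
#' Gaussian jitter is added per element and beat, clipped to preserve
#' per-element monotonicity.
#'
#' @param geometry One of `"planar"`, `"focal"`, `"collision"`, `"reentry"`.
#' @param nx,ny Grid size.
#' @param dx_cm Element edge (cm).
#' @param speed_cm_s Wave speed (cm/s).
#' @param n_beats Number of (paced) beats.
#' @param cycle_ms Beat cycle length (ms).
#' @param onset_ms First-beat onset (ms).
#' @param jitter_sd_ms SD of additive Gaussian timing jitter (ms).
#' @param seed RNG seed (mandatory when `jitter_sd_ms > 0`).
#' @param source Focal source element coordinates `c(ix, iy)`.
#' @param reentry_cycle_ms,reentry_duration_ms Rotor period and duration of
#'   the appended re-activation phase (geometry `"reentry"`).
#' @return An `activation_map` with a `ground_truth` attribute.
#' @export
gen_activation_map <- function(geometry = c("planar", "focal", "collision",
                                            "reentry"),
                               nx = 20, ny = 20, dx_cm = 0.025,
                               speed_cm_s = 45, n_beats = 5, cycle_ms = 1000,
                               onset_ms = 10, jitter_sd_ms = 0, seed = NULL,
                               source = c(1, 1), reentry_cycle_ms = 200,
                               reentry_duration_ms = 2000) {
  geometry <- match.arg(geometry)
  stopifnot(nx >= 1, ny >= 1, dx_cm > 0, speed_cm_s > 0, n_beats >= 1,
            cycle_ms > 0)
  v_cm_ms <- speed_cm_s / 1000
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  x <- (ix - 0.5) * dx_cm
  y <- (iy - 0.5) * dx_cm
  delay <- switch(geometry,
    planar = x / v_cm_ms,
    focal = sqrt((x - (source[1] - 0.5) * dx_cm)^2 +
                 (y - (source[2] - 0.5) * dx_cm)^2) / v_cm_ms,
    collision = pmin(x, (nx * dx_cm) - x) / v_cm_ms,
    reentry = x / v_cm_ms)
  beats <- outer(delay, onset_ms + (seq_len(n_beats) - 1) * cycle_ms, `+`)

  if (geometry == "reentry") {
    # rotor-like phase map around the grid center after pacing ends
    cxp <- nx * dx_cm / 2; cyp <- ny * dx_cm / 2
    phase <- (atan2(y - cyp, x - cxp) + pi) / (2 * pi)  # in [0, 1)
    t_start <- max(beats) + reentry_cycle_ms / 2
    k <- seq_len(max(1, floor(reentry_duration_ms / reentry_cycle_ms)))
    re <- outer(phase * reentry_cycle_ms,
                t_start + (k - 1) * reentry_cycle_ms, `+`)
    beats <- cbind(beats, re)
  }

  if (jitter_sd_ms > 0) {
    jit <- .with_seed(seed, matrix(stats::rnorm(length(beats), 0, jitter_sd_ms),
                                   nrow = nrow(beats)))
    beats <- beats + jit
  }
  times <- lapply(seq_len(nx * ny), function(e) {
    tt <- sort(beats[e, ])
    # clip to preserve monotonicity with a 1 ms floor between events
    if (length(tt) > 1)
      for (k in 2:length(tt)) tt[k] <- max(tt[k], tt[k - 1] + 1)
    tt
  })
  dur <- max(unlist(times)) + cycle_ms
  out <- activation_map(times, nx, ny, dx_cm, dur)
  attr(out, "ground_truth") <- list(
    kind = "activation_map", geometry = geometry, speed_cm_s = speed_cm_s,
    n_beats = n_beats, cycle_ms = cycle_ms, jitter_sd_ms = jitter_sd_ms,
    seed = seed, last_paced_ms = onset_ms + (n_beats - 1) * cycle_ms +
      max(delay))
  out
}

#' Generate a stylized action potential trace
#'
#' Piecewise-analytic waveform: linear upstroke, raised-cosine
#' repolarization, flat diastole, repeated with optional alternans
#' (alternating APD scaling). The repolarization span is chosen so that the
#' APD90 of each beat equals the requested value by construction.
#'
#' @param n_beats Number of APs.
#' @param cycle_ms Cycle length (ms).
#' @param apd_ms APD90 of odd beats (ms).
#' @param alternans_ratio Even-beat APD90 is `apd_ms * alternans_ratio`
#'   (1 = no alternans).
#' @param amplitude_mv AP amplitude (mV).
#' @param diastolic_mv Diastolic potential (mV).
#' @param upstroke_ms Upstroke duration (ms).
#' @param dt Sampling interval (ms).
#' @param onset_ms First upstroke onset.
#' @return A `voltage_trace` data frame with a `ground_truth` attribute.
#' @export
gen_ap_trace <- function(n_beats = 5, cycle_ms = 1000, apd_ms = 300,
                         alternans_ratio = 1, amplitude_mv = 100,
                         diastolic_mv = -75, upstroke_ms = 2, dt = 0.5,
                         onset_ms = 20) {
  stopifnot(n_beats >= 1, amplitude_mv > 0, upstroke_ms > 0, dt > 0,
            alternans_ratio > 0, apd_ms > upstroke_ms)
  apds <- apd_ms * ifelse(seq_len(n_beats) %% 2 == 1, 1, alternans_ratio)
  if (any(apds + upstroke_ms >= cycle_ms))
    stop("inconsistent timing: APD (plus upstroke) must be shorter than the cycle length")
  s90 <- acos(-0.8) / pi  # raised cosine reaches 90% repolarization here
  tt <- seq(0, onset_ms + n_beats * cycle_ms, by = dt)
  v <- rep(diastolic_mv, length(tt))
  for (b in seq_len(n_beats)) {
    t0 <- onset_ms + (b - 1) * cycle_ms
    repol_span <- (apds[b] - upstroke_ms) / s90
    up <- tt >= t0 & tt < t0 + upstroke_ms
    v[up] <- diastolic_mv + amplitude_mv * (tt[up] - t0) / upstroke_ms
    rp <- tt >= t0 + upstroke_ms & tt < t0 + upstroke_ms + repol_span
    s <- (tt[rp] - t0 - upstroke_ms) / repol_span
    v[rp] <- diastolic_mv + amplitude_mv * (1 + cos(pi * s)) / 2
  }
  out <- data.frame(time_ms = tt, v_m = v)
  class(out) <- c("voltage_trace", "data.frame")
  attr(out, "ground_truth") <- list(
    kind = "ap_trace", apd90_ms = apds, amplitude_mv = amplitude_mv,
    diastolic_mv = diastolic_mv, cycle_ms = cycle_ms,
    alternans_ratio = alternans_ratio, onset_ms = onset_ms,
    upstroke_ms = upstroke_ms)
  out
}

# Best-Fisher (1979) rejection sampler for von Mises angles.
.rvonmises <- function(n, kappa, mu = 0) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}

#' Generate a synthetic conduction-direction field
#'
#' Unit vectors with von Mises-distributed angles of concentration `kappa`
#' around a mean direction. The expected global heterogeneity index is the
#' closed form `1 - I1(kappa) / I0(kappa)` (Bessel-function ratio), stored
#' in the ground truth.
#'
#' @param n Number of vectors (>= 2).
#' @param kappa Angular concentration (>= 0; 0 = uniform).
#' @param mean_angle_deg Mean direction (degrees).
#' @param seed RNG seed (mandatory).
#' @return A `conduction_field` (unit vectors only) with a `ground_truth`
#'   attribute.
#' @export
gen_vector_field <- function(n, kappa, mean_angle_deg = 0, seed) {
  stopifnot(n >= 2)
  if (kappa < 0) stop("kappa must be non-negative")
  th <- .with_seed(seed, .rvonmises(n, kappa, mean_angle_deg * pi / 180))
  out <- structure(list(
    vx = NA_real_, vy = NA_real_, speed_cm_s = rep(NA_real_, n),
    ux = cos(th), uy = sin(th), valid = rep(TRUE, n),
    beat = NA_integer_, dx_cm = NA_real_, nx = n, ny = 1L),
    class = "conduction_field")
  attr(out, "ground_truth") <- list(
    kind = "vector_field", n = n, kappa = kappa,
    mean_angle_deg = mean_angle_deg, seed = seed,
    expected_heterogeneity = if (kappa == 0) 1 else
      1 - besselI(kappa, 1) / besselI(kappa, 0))
  out
}
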