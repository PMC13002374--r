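# Readout statistics: activation detection, beat irregularity (coefficient
# of variation of beat rate, in percent), conduction-velocity fields and the
# 0-1 conduction-heterogeneity index, action potential morphology metrics,
# and detection of pacing-induced sustained (fibrillation-like) activity.

#' Construct an activation map
#'
#' @param times List with one numeric vector of activation times (ms) per
#'   element, strictly increasing within each element.
#' @param nx,ny Grid dimensions (flat index `ix + (iy-1)*nx`).
#' @param dx_cm Element edge length (cm).
#' @param duration_ms Recording duration (ms).
#' @param threshold_mv,refractory_ms Detection parameters (metadata).
#' @return An `activation_map`.
#' @export
activation_map <- function(times, nx, ny, dx_cm, duration_ms,
                           threshold_mv = 0, refractory_ms = 0) {
  stopifnot(is.list(times), length(times) == nx * ny)
  for (tt in times) {
    if (length(tt) > 1 && any(diff(tt) <= 0))
      stop("activation times must be strictly increasing per element")
  }
  structure(list(times = times, nx = as.integer(nx), ny = as.integer(ny),
                 dx_cm = dx_cm, duration_ms = duration_ms,
                 threshold_mv = threshold_mv, refractory_ms = refractory_ms),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  counts <- lengths(x$times)
  cat(sprintf("activation map: %d x %d elements, %g ms, %d activations total\n",
              x$nx, x$ny, x$duration_ms, sum(counts)))
  cat(sprintf("  per-element count: min %d / median %g / max %d\n",
              min(counts), stats::median(counts), max(counts)))
  invisible(x)
}

#' Detect activations in a voltage trace
#'
#' An activation is registered at each upward crossing of the threshold
#' (default 0 mV), linearly interpolated between samples. Crossings inside
#' the refractory window of the previous event are ignored, and a
#' Schmitt-trigger hysteresis requires the voltage to fall at least
#' `hysteresis_mv` below threshold before the next crossing can register
#' (suppressing ripple double-counts at the crossing level).
#'
#' @param trace A `voltage_trace` data frame (`time_ms`, `v_m`) or numeric
#'   voltage vector with `times` supplied.
#' @param threshold_mv Threshold (mV).
#' @param refractory_ms Debounce window (ms).
#' @param times Sample times when `trace` is a bare numeric vector.
#' @param hysteresis_mv Re-arming depth below threshold (mV).
#' @return Numeric vector of event times (ms).
#' @export
detect_activations <- function(trace, threshold_mv = 0, refractory_ms = 0,
                               times = NULL, hysteresis_mv = 10) {
  if (is.data.frame(trace)) {
    times <- trace$time_ms
    v <- trace$v_m
  } else {
    v <- as.numeric(trace)
    if (is.null(times)) times <- seq_along(v) - 1
  }
  if (length(v) < 2) return(numeric(0))
  dtv <- diff(times)
  if (any(dtv <= 0) || (max(dtv) - min(dtv)) > 1e-6 * stats::median(dtv))
    stop("trace must be uniformly sampled")
  below <- v[-length(v)] < threshold_mv
  above <- v[-1] >= threshold_mv
  idx <- which(below & above)
  if (length(idx) == 0) return(numeric(0))
  # arming: the most recent excursion below (threshold - hysteresis) must
  # precede the crossing
  thr_low <- threshold_mv - hysteresis_mv
  armed_idx <- which(v < thr_low)
  if (length(armed_idx)) {
    # sequential: between consecutive kept crossings there must be a dip
    keep <- logical(length(idx))
    last_cross <- -Inf
    for (k in seq_along(idx)) {
      i <- idx[k]
      dipped <- any(armed_idx > last_cross & armed_idx <= i)
      if (dipped) {
        keep[k] <- TRUE
        last_cross <- i
      }
    }
    idx <- idx[keep]
  } else {
    idx <- integer(0)
  }
  if (length(idx) == 0) return(numeric(0))
  frac <- (threshold_mv - v[idx]) / (v[idx + 1] - v[idx])
  ev <- times[idx] + frac * dtv[idx]
  if (refractory_ms > 0 && length(ev) > 1) {
    keep <- ev[1]
    for (t in ev[-1]) if (t - keep[length(keep)] >= refractory_ms)
      keep <- c(keep, t)
    ev <- keep
  }
  ev
}

#' Construct a beat-event series
#'
#' @param times Ordered event times in ms (from an element, electrode, or
#'   contraction/calcium peak series).
#' @return A `beat_series` with derived inter-event intervals (ms) and
#'   instantaneous rates (min^-1).
#' @export
beat_series <- function(times) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("event times must be strictly increasing")
  iv <- diff(times)
  structure(list(times = times, intervals_ms = iv, rates_bpm = 60000 / iv),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("beat series: %d events", length(x$times)))
  if (length(x$times) >= 3)
    cat(sprintf(", mean rate %.1f min^-1", mean(x$rates_bpm)))
  cat("\n")
  invisible(x)
}

#' Beat irregularity (coefficient of variation of beat rate)
#'
#' Irregularity (%) = SD(beat rate) / mean(beat rate) x 100, where the beat
#' rate is the instantaneous per-interval rate 60000 / interval_ms. Zero if
#' and only if all rates are equal.
#'
#' @param series A [beat_series()] or numeric vector of event times (ms);
#'   at least 3 events (2 rates) are required.
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @return An `irregularity_result`: `irregularity_pct`, `n_beats`,
#'   `mean_rate_bpm`, `sd_rate_bpm`, `sd_mode`.
#' @export
beat_irregularity <- function(series, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (!inherits(series, "beat_series")) series <- beat_series(series)
  n <- length(series$times)
  if (n < 3) stop("insufficient beats: at least 3 events are required")
  r <- series$rates_bpm
  s <- stats::sd(r)
  if (sd_mode == "population") s <- s * sqrt((length(r) - 1) / length(r))
  m <- mean(r)
  structure(list(irregularity_pct = 100 * s / m, n_beats = n,
                 mean_rate_bpm = m, sd_rate_bpm = s, sd_mode = sd_mode,
                 aggregation = "single"),
            class = "irregularity_result")
}

#' @export
print.irregularity_result <- function(x, ...) {
  cat(sprintf(
    "beat irregularity: %.2f%% (n = %d beats, mean rate %.1f min^-1, %s SD, %s)\n",
    x$irregularity_pct, x$n_beats, x$mean_rate_bpm, x$sd_mode, x$aggregation))
  invisible(x)
}

#' Tissue-level beat irregularity
#'
#' Computes per-element beat irregularity across an activation map and
#' aggregates with the configured statistic (default: median across
#' elements). Elements with fewer than 3 activations are excluded and
#' counted.
#'
#' @param map An `activation_map`.
#' @param aggregation `"median"` or `"mean"`.
#' @param sd_mode Passed to [beat_irregularity()].
#' @param from_ms Discard activations before this time (ms), e.g. to
#'   exclude the initial adjustment transient after remodeling is switched
#'   on; default 0 (use the full recording).
#' @return An `irregularity_result` with `per_element` values and
#'   `n_excluded` attached.
#' @export
tissue_irregularity <- function(map, aggregation = c("median", "mean"),
                                sd_mode = c("sample", "population"),
                                from_ms = 0) {
  stopifnot(inherits(map, "activation_map"))
  aggregation <- match.arg(aggregation)
  sd_mode <- match.arg(sd_mode)
  if (from_ms > 0)
    map$times <- lapply(map$times, function(tt) tt[tt >= from_ms])
  ok <- lengths(map$times) >= 3
  if (!any(ok)) stop("all elements excluded: no element has >= 3 activations")
  vals <- vapply(map$times[ok], function(tt)
    beat_irregularity(tt, sd_mode)$irregularity_pct, 0)
  rates <- vapply(map$times[ok], function(tt) mean(60000 / diff(tt)), 0)
  agg <- if (aggregation == "median") stats::median(vals) else mean(vals)
  structure(list(irregularity_pct = agg,
                 n_beats = sum(lengths(map$times)),
                 mean_rate_bpm = stats::median(rates),
                 sd_rate_bpm = NA_real_, sd_mode = sd_mode,
                 aggregation = aggregation,
                 per_element = vals, n_excluded = sum(!ok),
                 n_elements = length(map$times)),
            class = "irregularity_result")
}

#' Conduction-velocity vector field from an activation map
#'
#' Central finite differences on the activation-time surface of one beat
#' give the time gradient g = grad(T) (ms/cm); the velocity vector is
#' g / |g|^2 (reported in cm/s) and the conduction direction is the unit
#' vector g / |g|. Elements whose gradient magnitude falls below
#' `grad_floor` (near-simultaneous activation) are marked invalid, as are
#' elements without the requested beat in their finite-difference stencil.
#'
#' @param map An `activation_map`.
#' @param beat 1-based beat index per element.
#' @param grad_floor Minimal |g| in ms/cm (default 1: speeds above 10 m/s
#'   are treated as undefined).
#' @return A `conduction_field` with matrices `vx`, `vy`, `speed_cm_s`,
#'   `ux`, `uy` and logical `valid`.
#' @export
conduction_field <- function(map, beat = 1, grad_floor = 1) {
  stopifnot(inherits(map, "activation_map"))
  nx <- map$nx; ny <- map$ny
  tt <- matrix(NA_real_, nx, ny)
  has <- lengths(map$times) >= beat
  tt[has] <- vapply(map$times[has], `[[`, 0, beat)
  gx <- gy <- matrix(NA_real_, nx, ny)
  h2 <- 2 * map$dx_cm
  if (nx >= 3)
    gx[2:(nx - 1), ] <- (tt[3:nx, ] - tt[1:(nx - 2), ]) / h2
  if (ny >= 3)
    gy[, 2:(ny - 1)] <- (tt[, 3:ny] - tt[, 1:(ny - 2)]) / h2
  gmag <- sqrt(gx^2 + gy^2)
  valid <- is.finite(gmag) & gmag >= grad_floor
  speed <- ifelse(valid, 1 / gmag, NA_real_)      # cm/ms
  ux <- ifelse(valid, gx / gmag, NA_real_)
  uy <- ifelse(valid, gy / gmag, NA_real_)
  structure(list(vx = 1000 * speed * ux, vy = 1000 * speed * uy,
                 speed_cm_s = 1000 * speed, ux = ux, uy = uy,
                 valid = valid, beat = beat, dx_cm = map$dx_cm,
                 nx = nx, ny = ny),
            class = "conduction_field")
}

#' @export
print.conduction_field <- function(x, ...) {
  nv <- sum(x$valid, na.rm = TRUE)
  cat(sprintf("conduction field (beat %d): %d valid elements", x$beat, nv))
  if (nv > 0)
    cat(sprintf(", median speed %.1f cm/s",
                stats::median(x$speed_cm_s[x$valid], na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Conduction-direction heterogeneity index
#'
#' Circular dispersion of conduction-direction unit vectors on a 0-1 scale:
#' 0 for perfectly aligned vectors, 1 for maximal disorder. Global mode is
#' the circular variance `1 - |mean unit vector|` over all valid elements;
#' local mode averages the circular variance over each element's 3x3
#' neighborhood.
#'
#' @param field A `conduction_field`, or a two-column matrix/data frame of
#'   unit-vector components.
#' @param mode `"global"` (default) or `"local"`.
#' @return Heterogeneity index in `[0, 1]`.
#' @export
heterogeneity_index <- function(field, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (inherits(field, "conduction_field")) {
    ux <- field$ux; uy <- field$uy; valid <- field$valid
  } else {
    m <- as.matrix(field)
    stopifnot(ncol(m) == 2)
    ux <- m[, 1]; uy <- m[, 2]
    valid <- is.finite(ux) & is.finite(uy)
    if (mode == "local") stop("local mode requires a conduction_field")
  }
  if (sum(valid, na.rm = TRUE) < 2)
    stop("at least 2 valid conduction vectors are required")
  circ_var <- function(x, y) 1 - sqrt(mean(x)^2 + mean(y)^2)
  sel <- valid & is.finite(ux) & is.finite(uy)
  if (mode == "global") return(circ_var(ux[sel], uy[sel]))
  nx <- field$nx; ny <- field$ny
  out <- c()
  for (iy in 2:(ny - 1)) for (ix in 2:(nx - 1)) {
    sel_x <- (ix - 1):(ix + 1); sel_y <- (iy - 1):(iy + 1)
    vv <- field$valid[sel_x, sel_y]
    if (sum(vv, na.rm = TRUE) >= 2)
      out <- c(out, circ_var(field$ux[sel_x, sel_y][vv],
                             field$uy[sel_x, sel_y][vv]))
  }
  if (length(out) == 0) stop("no 3x3 neighborhood has >= 2 valid vectors")
  mean(out)
}

#' Action potential morphology metrics
#'
#' Per beat: amplitude (peak minus preceding diastolic minimum), maximum
#' diastolic potential, maximum upstroke velocity, APD90 (activation at
#' maximal dV/dt to 90% repolarization of the amplitude) and AUC90 (area
#' between the voltage and the 90%-repolarization level over the APD90
#' window). Across-beat variability is reported as SD/mean x 100 for APD90
#' and AUC90 (an alternans-sensitive variance statistic).
#'
#' @param trace A `voltage_trace` data frame (`time_ms`, `v_m`).
#' @param events Upstroke event times (ms); detected with
#'   [detect_activations()] at `threshold_mv` when `NULL`.
#' @param refractory_ms Debounce used when detecting events.
#' @param threshold_mv Detection threshold for the implicit event search
#'   (morphology measurements themselves are threshold-free).
#' @return An `ap_metrics` object: per-beat data frame `beats` plus
#'   `apd90_var_pct`, `auc90_var_pct`, `n_beats`, `n_dropped`.
#' @export
ap_metrics <- function(trace, events = NULL, refractory_ms = 100,
                       threshold_mv = 0) {
  stopifnot(is.data.frame(trace), nrow(trace) > 2)
  tt <- trace$time_ms; v <- trace$v_m
  if (is.null(events))
    events <- detect_activations(trace, threshold_mv, refractory_ms)
  if (length(events) < 2) stop("at least 2 complete action potentials are required")
  dropped <- 0L
  rows <- list()
  bounds <- c(tt[1], events, tt[length(tt)])
  for (k in seq_along(events)) {
    ev <- events[k]
    seg_lo <- bounds[k]          # previous event (or trace start)
    seg_hi <- bounds[k + 2]      # next event (or trace end)
    pre <- tt >= seg_lo & tt <= ev
    post <- tt >= ev & tt <= seg_hi
    if (sum(pre) < 2 || sum(post) < 3) { dropped <- dropped + 1L; next }
    mdp <- min(v[pre])
    vpost <- v[post]; tpost <- tt[post]
    ipk <- which.max(vpost)
    peak <- vpost[ipk]
    amp <- peak - mdp
    v90 <- peak - 0.9 * amp
    # activation time: maximal dV/dt around the threshold crossing
    win <- tt >= ev - 20 & tt <= ev + 20
    dv <- diff(v[win]) / diff(tt[win])
    act_t <- tt[win][which.max(dv)]
    vmax_up <- max(dv)
    # first downward crossing of the 90% level after the peak
    after <- seq(ipk, length(vpost))
    cross <- which(vpost[after][-1] <= v90 & vpost[after][-length(after)] > v90)
    if (length(cross) == 0) { dropped <- dropped + 1L; next }
    i0 <- after[cross[1]]
    f <- (v90 - vpost[i0]) / (vpost[i0 + 1] - vpost[i0])
    t90 <- tpost[i0] + f * (tpost[i0 + 1] - tpost[i0])
    apd90 <- t90 - act_t
    # AUC90: trapezoidal integral of (V - V90) from activation to t90
    sel <- tpost >= act_t & tpost <= t90
    ts <- c(tpost[sel], t90)
    vs <- c(vpost[sel] - v90, 0)
    auc90 <- sum(diff(ts) * (head(vs, -1) + tail(vs, -1)) / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      event_ms = ev, activation_ms = act_t, peak_mv = peak, mdp_mv = mdp,
      amplitude_mv = amp, upstroke_v_s = vmax_up, apd90_ms = apd90,
      auc90_mv_ms = auc90, t90_ms = t90)
  }
  if (dropped > 0)
    warning(sprintf("%d incomplete (unrepolarized or truncated) AP(s) dropped",
                    dropped))
  if (length(rows) == 0) stop("no complete action potential could be measured")
  beats <- do.call(rbind, rows)
  var_pct <- function(x) if (length(x) < 2) NA_real_ else
    100 * stats::sd(x) / abs(mean(x))
  structure(list(beats = beats, n_beats = nrow(beats), n_dropped = dropped,
                 apd90_var_pct = var_pct(beats$apd90_ms),
                 auc90_var_pct = var_pct(beats$auc90_mv_ms)),
            class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf(
    "AP metrics: %d beats | APD90 %.1f ms (var %.2f%%) | AUC90 var %.2f%% | amplitude %.1f mV\n",
    x$n_beats, mean(x$beats$apd90_ms), x$apd90_var_pct, x$auc90_var_pct,
    mean(x$beats$amplitude_mv)))
  invisible(x)
}

#' Detect pacing-induced sustained (fibrillation-like) activity
#'
#' Classifies a run as sustained when at least `min_fraction` of elements
#' register `min_activations` or more activations after the last stimulus
#' plus a blanking interval (which absorbs the directly paced response).
#'
#' @param map An `activation_map`.
#' @param last_stimulus_ms Time of the final stimulus pulse (ms).
#' @param window_ms Observation window after the last stimulus (ms,
#'   default 2000); the recording must extend that far.
#' @param blanking_ms Blanking after the last stimulus (ms, default 50).
#' @param min_fraction Fraction of elements required (default 0.25).
#' @param min_activations Post-blanking activation count per element
#'   (default 2).
#' @return List: `sustained` (logical), `fraction_active`, `extra_counts`
#'   (per-element post-blanking activation counts).
#' @export
detect_sustained_activity <- function(map, last_stimulus_ms,
                                      window_ms = 2000, blanking_ms = 50,
                                      min_fraction = 0.25,
                                      min_activations = 2) {
  stopifnot(inherits(map, "activation_map"))
  if (window_ms <= 0) stop("window_ms must be positive")
  if (map$duration_ms < last_stimulus_ms + window_ms)
    stop(sprintf("recording too short: extends to %g ms, need %g ms",
                 map$duration_ms, last_stimulus_ms + window_ms))
  t0 <- last_stimulus_ms + blanking_ms
  counts <- vapply(map$times, function(tt) sum(tt > t0), 0L)
  frac <- mean(counts >= min_activations)
  list(sustained = frac >= min_fraction, fraction_active = frac,
       extra_counts = counts)
}

#' Activation map to long data frame
#'
#' @param map An `activation_map`.
#' @return Data frame with columns `element`, `ix`, `iy`, `beat`,
#'   `time_ms`.
#' @export
activation_map_to_df <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  counts <- lengths(map$times)
  el <- rep(seq_along(map$times), counts)
  data.frame(element = el,
             ix = (el - 1L) %% map$nx + 1L,
             iy = (el - 1L) %/% map$nx + 1L,
             beat = unlist(lapply(counts, seq_len), use.names = FALSE),
             time_ms = unlist(map$times, use.names = FALSE))
}

#' Write / read an activation map as CSV
#'
#' The CSV holds one row per activation (`element, ix, iy, beat, time_ms`);
#' grid shape and detection metadata travel in a `#`-prefixed header line.
#'
#' @param map An `activation_map`.
#' @param path Output CSV path.
#' @return `write_activation_csv`: the path, invisibly;
#'   `read_activation_csv`: the reconstructed `activation_map`.
#' @export
write_activation_csv <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  hdr <- sprintf("# nx=%d ny=%d dx_cm=%.10g duration_ms=%.10g threshold_mv=%.10g refractory_ms=%.10g",
                 map$nx, map$ny, map$dx_cm, map$duration_ms,
                 map$threshold_mv, map$refractory_ms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(activation_map_to_df(map), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activation_csv
#' @export
read_activation_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.e+]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.csv(path, skip = 1)
  n_el <- meta[["nx"]] * meta[["ny"]]
  times <- rep(list(numeric(0)), n_el)
  if (nrow(df) > 0) {
    sp <- split(df$time_ms, factor(df$element, levels = seq_len(n_el)))
    times <- unname(lapply(sp, function(x) sort(as.numeric(x))))
  }
  activation_map(times, meta[["nx"]], meta[["ny"]], meta[["dx_cm"]],
                 meta[["duration_ms"]], meta[["threshold_mv"]],
                 meta[["refractory_ms"]])
}
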