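# Monodomain tissue: structured 2D grids with per-element conductivity and
# current scalers, no-flux boundaries, and the operator-split solver driver.
#
# Grid convention: per-element fields are nx-by-ny matrices; rows index x.
# The flat element index is ix + (iy - 1) * nx, matching R's column-major
# layout. Elements with negative diffusivity are non-tissue (e.g. the
# pseudo-atria septum): excluded from the reaction step and treated as
# zero-flux walls by the diffusion operator.

#' Build a uniform square (or rectangular) tissue grid
#'
#' @param nx,ny Element counts along x and y.
#' @param dx_um Element edge length in micrometers (default 250).
#' @param base_diffusivity Monodomain diffusivity (cm^2/ms) of control
#'   tissue; the model's calibrated control value when `NULL`.
#' @param model Ionic model of the tissue: `"hipsc"` or `"atrial"`.
#' @return A `tissue_grid` with uniform control properties, named regions
#'   `tissue` (all elements) and `pacing_site` (a two-column strip on the
#'   west edge), and total area `nx * ny * dx^2` in cm^2.
#' @export
build_square_tissue <- function(nx, ny, dx_um = 250, base_diffusivity = NULL,
                                model = c("hipsc", "atrial")) {
  model <- match.arg(model)
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1)
    stop("nx and ny must be positive")
  if (!is.numeric(dx_um) || dx_um <= 0) stop("dx_um must be positive")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.null(base_diffusivity))
    base_diffusivity <- .model_default(model, "diffusivity")
  stopifnot(base_diffusivity > 0)
  dx_cm <- dx_um * 1e-4
  n_el <- nx * ny
  ix <- rep(seq_len(nx), times = ny)
  regions <- list(
    tissue = seq_len(n_el),
    pacing_site = which(ix <= min(2L, nx))
  )
  structure(list(
    nx = nx, ny = ny, dx_cm = dx_cm, model = model,
    base_diffusivity = base_diffusivity,
    D = matrix(base_diffusivity, nx, ny),
    s_na = matrix(1, nx, ny), s_nak = matrix(1, nx, ny),
    regions = regions,
    area_cm2 = n_el * dx_cm^2
  ), class = "tissue_grid")
}

#' Configuration for the idealized two-chamber pseudo-atria
#'
#' A desk-scale 2D reduction of the atria: two rectangular chambers (right
#' and left) joined by a conducting bridge through a non-conducting septum,
#' venous sub-zones along the superior border, and a sinus-node pacing site
#' on the superior right-atrial border.
#'
#' @param nx,ny Element counts (default 80 x 50).
#' @param dx_um Element edge (default 500 um, total 4 x 2.5 cm).
#' @param base_diffusivity Control diffusivity (cm^2/ms); atrial-model
#'   calibrated default when `NULL`.
#' @param septum_cols Width of the septum in elements (default 2).
#' @param bridge_rows Height of the interatrial conducting bridge in
#'   elements (default 8); zero is rejected.
#' @param venous_frac Fraction of each chamber's height forming the
#'   superior venous zone (default 0.3).
#' @return A list of class `pseudo_atria_config`.
#' @export
pseudo_atria_config <- function(nx = 80, ny = 50, dx_um = 500,
                                base_diffusivity = NULL, septum_cols = 2,
                                bridge_rows = 8, venous_frac = 0.3) {
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx_um = dx_um,
                 base_diffusivity = base_diffusivity,
                 septum_cols = as.integer(septum_cols),
                 bridge_rows = as.integer(bridge_rows),
                 venous_frac = venous_frac),
            class = "pseudo_atria_config")
}

#' Build the idealized two-chamber pseudo-atria grid
#'
#' @param config A [pseudo_atria_config()].
#' @return A `tissue_grid` (atrial model) with regions `RA`, `LA`,
#'   `venous_ra`, `venous_la`, `bridge`, `pacing_site` and `tissue` (all
#'   active elements). Septum elements are non-tissue.
#' @export
build_pseudo_atria <- function(config = pseudo_atria_config()) {
  cf <- config
  if (!inherits(cf, "pseudo_atria_config")) stop("config must be a pseudo_atria_config")
  if (cf$bridge_rows < 1) stop("zero-width bridge: chambers would be disconnected")
  if (cf$nx < cf$septum_cols + 6 || cf$ny < 4) stop("pseudo-atria grid too small")
  g <- build_square_tissue(cf$nx, cf$ny, cf$dx_um, cf$base_diffusivity,
                           model = "atrial")
  nx <- g$nx; ny <- g$ny
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)

  s0 <- floor((nx - cf$septum_cols) / 2) + 1L
  septum_x <- s0:(s0 + cf$septum_cols - 1L)
  b0 <- floor((ny - cf$bridge_rows) / 2) + 1L
  bridge_y <- b0:(b0 + cf$bridge_rows - 1L)

  in_septum_x <- ix %in% septum_x
  in_bridge <- in_septum_x & (iy %in% bridge_y)
  septum <- which(in_septum_x & !(iy %in% bridge_y))
  ra <- which(ix < s0)
  la <- which(ix > s0 + cf$septum_cols - 1L)
  venous_y <- iy > ny - max(1L, round(cf$venous_frac * ny))
  venous_ra <- which(ix < s0 & venous_y)
  venous_la <- which(ix > s0 + cf$septum_cols - 1L & venous_y)
  pacing <- which(ix <= 3L & iy > ny - 3L)

  g$D[septum] <- -1  # non-tissue
  g$regions <- list(
    tissue = which(as.vector(g$D) > 0),
    RA = ra, LA = la, venous_ra = venous_ra, venous_la = venous_la,
    bridge = which(in_bridge), pacing_site = pacing
  )
  for (nm in names(g$regions))
    if (length(g$regions[[nm]]) == 0)
      stop(sprintf("pseudo-atria region '%s' is empty", nm))

  if (!.grid_connected(g))
    stop("pseudo-atria chambers are not mutually reachable (disconnected grid)")
  g$area_cm2 <- length(g$regions$tissue) * g$dx_cm^2
  g
}

# Breadth-first connectivity over active elements (4-neighborhood).
.grid_connected <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  act <- as.vector(grid$D) > 0
  start <- which(act)[1]
  seen <- logical(nx * ny)
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    ix <- (e - 1L) %% nx + 1L; iy <- (e - 1L) %/% nx + 1L
    nb <- c(if (ix > 1) e - 1L, if (ix < nx) e + 1L,
            if (iy > 1) e - nx, if (iy < ny) e + nx)
    nb <- nb[act[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen[act])
}

#' Flat element index from grid coordinates
#'
#' @param grid A `tissue_grid`.
#' @param ix,iy 1-based element coordinates.
#' @return 1-based flat element index.
#' @export
element_index <- function(grid, ix, iy) {
  stopifnot(all(ix >= 1), all(ix <= grid$nx), all(iy >= 1), all(iy <= grid$ny))
  as.integer(ix + (iy - 1L) * grid$nx)
}

#' @export
print.tissue_grid <- function(x, ...) {
  n_act <- sum(as.vector(x$D) > 0)
  cat(sprintf(
    "tissue grid (%s model): %d x %d elements, dx %g um, area %.4g cm^2\n",
    x$model, x$nx, x$ny, x$dx_cm * 1e4, x$area_cm2))
  cat(sprintf("  active elements: %d | base diffusivity %.4g cm^2/ms\n",
              n_act, x$base_diffusivity))
  rem <- sum(x$s_na != 1 | x$s_nak != 1 | (x$D > 0 & abs(x$D - x$base_diffusivity) > 1e-12))
  cat(sprintf("  remodeled elements: %d | regions: %s\n", rem,
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

# Auto-select a CFL-safe diffusion macro step (integer multiple of dt_r).
.auto_dt_diffusion <- function(grid, dt_r, cap = 0.1) {
  dmax <- max(c(0, as.vector(grid$D)[as.vector(grid$D) > 0]))
  cfl <- if (dmax > 0) grid$dx_cm^2 / (4 * dmax) else Inf
  if (cfl < dt_r)
    stop(sprintf(
      "CFL violation: dt_diffusion must be <= %g ms (and >= dt_reaction %g); reduce diffusivity or dt_reaction",
      cfl, dt_r))
  dt_r * max(1, floor(min(cap, cfl) / dt_r + 1e-9))
}

# Choose both time steps: the model's default reaction dt, lowered (on a
# 2 us quantum, to bound the number of distinct lookup tables) when the
# diffusion CFL bound at this grid's diffusivity requires it.
.auto_dts <- function(grid, dt_r = NULL) {
  if (is.null(dt_r)) dt_r <- .model_default(grid$model, "tissue_dt_cap")
  dmax <- max(c(0, as.vector(grid$D)[as.vector(grid$D) > 0]))
  cfl <- if (dmax > 0) 0.999 * grid$dx_cm^2 / (4 * dmax) else Inf
  if (cfl < dt_r) dt_r <- floor(cfl / 0.002) * 0.002
  if (dt_r <= 0)
    stop(sprintf(
      "CFL violation: maximal admissible time step %g ms is below the 2 us floor; reduce diffusivity or refine dx",
      cfl))
  list(dt_r = dt_r, dt_d = dt_r * max(1, floor(min(0.1, cfl) / dt_r + 1e-9)))
}

# Slow-cache cadence: light refresh about every 0.1 ms, heavy every ~1 ms.
.refresh_args <- function(dt_d) {
  re <- max(1L, as.integer(round(0.1 / dt_d)))
  list(refresh_every = re, heavy_every = 10L)
}

#' Advance tissue states by operator-split monodomain steps
#'
#' Each macro step applies the ionic reaction (Rush-Larsen / forward Euler
#' sub-steps) followed by an explicit 5-point-Laplacian diffusion update
#' with harmonic-mean interface diffusivity and no-flux boundaries
#' (Godunov splitting).
#'
#' @param grid A `tissue_grid`.
#' @param states `n_state x n_elements` state matrix (a single column is
#'   recycled to all elements); `NULL` starts from the settled state.
#' @param dt_reaction Reaction sub-step (ms); model default if `NULL`.
#' @param dt_diffusion Diffusion macro step (ms); must be an integer
#'   multiple of `dt_reaction` and satisfy the CFL bound
#'   `dt <= dx^2 / (4 max D)`; auto-selected if `NULL`.
#' @param n_steps Number of macro steps.
#' @param reaction If `FALSE`, only the diffusion operator is applied
#'   (useful for conservation checks).
#' @return Updated `n_state x n_elements` state matrix.
#' @export
step_monodomain <- function(grid, states = NULL, dt_reaction = NULL,
                            dt_diffusion = NULL, n_steps = 1,
                            reaction = TRUE) {
  stopifnot(inherits(grid, "tissue_grid"), n_steps >= 1)
  if (is.null(dt_reaction)) {
    dts <- .auto_dts(grid)
    dt_reaction <- dts$dt_r
    if (is.null(dt_diffusion)) dt_diffusion <- dts$dt_d
  }
  if (is.null(dt_diffusion)) dt_diffusion <- .auto_dt_diffusion(grid, dt_reaction)
  n_el <- grid$nx * grid$ny
  if (is.null(states)) states <- matrix(settled_state(grid$model), ncol = 1)
  if (!is.matrix(states) || (ncol(states) != n_el && ncol(states) != 1))
    stop("states must be an n_state x n_elements matrix matching the grid")
  ra <- .refresh_args(dt_diffusion)
  res <- .cm_sim_run(.model_id(grid$model), grid$nx, grid$ny,
                     as.vector(grid$D), grid$dx_cm,
                     as.vector(grid$s_na), as.vector(grid$s_nak), states,
                     list(), n_steps * dt_diffusion, dt_reaction,
                     dt_diffusion, integer(0), 0, 0.0,
                     .model_default(grid$model, "refractory"), 0L,
                     isTRUE(reaction), 1e6,
                     ra$refresh_every, ra$heavy_every)
  res$state
}

#' Run a tissue simulation
#'
#' Simulates the monodomain tissue under a stimulus protocol and registers
#' an activation for every element at each upward threshold crossing
#' (default 0 mV, linearly interpolated, with a refractory debounce).
#'
#' @param grid A `tissue_grid`.
#' @param protocol A [stimulus_protocol()] (e.g. [spontaneous_protocol()]).
#' @param duration_ms Simulated duration; protocol duration if `NULL`.
#' @param dt_reaction,dt_diffusion Time steps (ms); model default /
#'   CFL-auto when `NULL`.
#' @param probes 1-based element indices whose voltage traces are recorded.
#' @param probe_dt Probe sampling interval (ms).
#' @param frame_dt Full-field snapshot interval (ms); 0 disables frames.
#' @param init Initial state matrix (single column recycled); settled state
#'   if `NULL`.
#' @param threshold_mv Activation registration threshold (mV); model
#'   default if `NULL` (0 mV hiPSC; -60 mV atrial, whose propagating
#'   upstroke overshoots only a few mV at desk-scale element sizes).
#' @param refractory_ms Debounce window between activations; model default
#'   if `NULL` (100 ms hiPSC, 50 ms atrial).
#' @param seed Recorded in the metadata for provenance (the solver itself
#'   is deterministic).
#' @return A `simulation_result`: `activation_map`, probe traces, final
#'   states, diagnostics, and reproducibility metadata. If the integration
#'   blows up the partial result is returned with `blowup = TRUE` and a
#'   warning.
#' @export
run_tissue <- function(grid, protocol, duration_ms = NULL,
                       dt_reaction = NULL, dt_diffusion = NULL,
                       probes = NULL, probe_dt = 1, frame_dt = 0,
                       init = NULL, threshold_mv = NULL,
                       refractory_ms = NULL, seed = NULL) {
  stopifnot(inherits(grid, "tissue_grid"),
            inherits(protocol, "stimulus_protocol"))
  model <- grid$model
  if (is.null(duration_ms)) duration_ms <- protocol$duration_ms
  stopifnot(duration_ms >= 0)
  if (is.null(dt_reaction)) {
    dts <- .auto_dts(grid)
    dt_reaction <- dts$dt_r
    if (is.null(dt_diffusion)) dt_diffusion <- dts$dt_d
  }
  if (is.null(dt_diffusion)) dt_diffusion <- .auto_dt_diffusion(grid, dt_reaction)
  if (is.null(refractory_ms)) refractory_ms <- .model_default(model, "refractory")
  if (is.null(threshold_mv)) threshold_mv <- .model_default(model, "threshold_mv")
  n_el <- grid$nx * grid$ny
  if (is.null(init)) init <- matrix(settled_state(model), ncol = 1)
  if (is.null(probes)) probes <- integer(0)
  probes <- as.integer(probes)
  stopifnot(all(probes >= 1), all(probes <= n_el))

  trains <- .resolve_trains(protocol, grid$regions, n_el,
                            .model_default(model, "stim_amplitude"))
  frame_every <- if (frame_dt > 0)
    max(1L, as.integer(round(frame_dt / dt_diffusion))) else 0L

  if (duration_ms == 0) {
    amap <- activation_map(rep(list(numeric(0)), n_el), grid$nx, grid$ny,
                           grid$dx_cm, 0, threshold_mv, refractory_ms)
    return(structure(list(
      activation_map = amap, probe_t = numeric(0),
      probe_v = matrix(0, 0, length(probes)), probe_elements = probes,
      frames = NULL, frame_t = numeric(0), state_final = init,
      blowup = FALSE, blowup_time = NA_real_, gate_clamp_count = 0,
      meta = .run_meta(grid, protocol, duration_ms, dt_reaction,
                       dt_diffusion, threshold_mv, refractory_ms, seed)),
      class = "simulation_result"))
  }

  ra <- .refresh_args(dt_diffusion)
  res <- .cm_sim_run(.model_id(model), grid$nx, grid$ny, as.vector(grid$D),
                     grid$dx_cm, as.vector(grid$s_na), as.vector(grid$s_nak),
                     init, trains, duration_ms, dt_reaction, dt_diffusion,
                     probes - 1L, probe_dt, threshold_mv, refractory_ms,
                     frame_every, TRUE, 200.0,
                     ra$refresh_every, ra$heavy_every)
  if (isTRUE(res$blowup))
    warning(sprintf("integration blow-up at t = %.2f ms; returning partial result",
                    res$blowup_time))
  amap <- activation_map(res$activations, grid$nx, grid$ny, grid$dx_cm,
                         duration_ms, threshold_mv, refractory_ms)
  structure(list(
    activation_map = amap,
    probe_t = res$probe_t,
    probe_v = res$probe_v,
    probe_elements = probes,
    frames = if (frame_every > 0) res$frames else NULL,
    frame_t = if (frame_every > 0) res$frame_t else numeric(0),
    state_final = res$state,
    blowup = isTRUE(res$blowup), blowup_time = res$blowup_time,
    gate_clamp_count = res$gate_clamp_count,
    meta = .run_meta(grid, protocol, duration_ms, dt_reaction, dt_diffusion,
                     threshold_mv, refractory_ms, seed)),
    class = "simulation_result")
}

.run_meta <- function(grid, protocol, duration_ms, dt_reaction, dt_diffusion,
                      threshold_mv, refractory_ms, seed) {
  cfg <- list(model = grid$model, nx = grid$nx, ny = grid$ny,
              dx_cm = grid$dx_cm, base_diffusivity = grid$base_diffusivity,
              D = as.vector(grid$D), s_na = as.vector(grid$s_na),
              s_nak = as.vector(grid$s_nak),
              protocol = unclass_recursive(protocol),
              duration_ms = duration_ms, dt_reaction = dt_reaction,
              dt_diffusion = dt_diffusion, threshold_mv = threshold_mv,
              refractory_ms = refractory_ms,
              seed = if (is.null(seed)) NA else seed)
  list(model = grid$model, nx = grid$nx, ny = grid$ny, dx_cm = grid$dx_cm,
       duration_ms = duration_ms, dt_reaction = dt_reaction,
       dt_diffusion = dt_diffusion, threshold_mv = threshold_mv,
       refractory_ms = refractory_ms, seed = if (is.null(seed)) NA else seed,
       package_version = as.character(utils::packageVersion("cardiomod")),
       config_hash = config_hash(cfg))
}

# Strip S3 classes so a nested object serializes plainly to JSON.
unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; used for resumable suites and
#' result provenance.
#'
#' @param x Any JSON-serializable R object.
#' @return Character MD5 digest.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass_recursive(x), auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.simulation_result <- function(x, ...) {
  counts <- lengths(x$activation_map$times)
  cat(sprintf(
    "simulation result (%s): %d x %d elements, %g ms simulated\n",
    x$meta$model, x$meta$nx, x$meta$ny, x$meta$duration_ms))
  cat(sprintf("  activations per element: min %d / median %g / max %d\n",
              min(counts), stats::median(counts), max(counts)))
  if (x$blowup) cat(sprintf("  ** blow-up at %.2f ms (partial result)\n",
                            x$blowup_time))
  invisible(x)
}
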