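# Configuration parsing (YAML, units normalized to ms / cm / mV) and the
# scenario-suite driver that ties mesh construction, remodeling, simulation
# and analysis together into a resumable results directory.

.cfg_keys <- c("experiment", "mesh", "duration_ms", "duration_s",
               "intensities", "patch_radius_cm", "patch_radius_mm",
               "target_fraction", "seeds", "threshold_mv", "dt_reaction_ms",
               "outdir")
.mesh_keys <- c("nx", "ny", "dx_um", "dx_mm", "dx_cm")

#' Parse and validate a suite configuration
#'
#' Reads a YAML file (or takes an equivalent list), rejects unknown keys,
#' fills documented defaults and normalizes units to milliseconds,
#' centimeters and millivolts.
#'
#' Defaults: mesh 40 x 40 at dx = 250 um (hiPSC suite) or 80 x 50 at
#' 500 um (pseudo-atria suite); duration 20 s (hiPSC; the atria suite
#' always uses its stress-pacing protocol length); intensities 0.5; patch
#' radius 0.5 cm (both suites); target fraction 0.5; activation
#' threshold 0 mV. `seeds` is mandatory.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return A normalized `cardiomod_config` list.
#' @export
parse_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .cfg_keys)
  if (length(unknown))
    stop(sprintf("unknown config key: '%s'", unknown[1]))
  if (is.null(config$experiment))
    stop("missing mandatory config key: 'experiment'")
  experiment <- match.arg(config$experiment, c("hipsc_suite", "atria_suite"))
  if (is.null(config$seeds))
    stop("missing mandatory config key: 'seeds' (seeds are never defaulted)")
  seeds <- as.integer(config$seeds)
  if (length(seeds) < 1 || anyNA(seeds)) stop("'seeds' must be integers")

  mesh <- config$mesh
  if (!is.null(mesh)) {
    um <- setdiff(names(mesh), .mesh_keys)
    if (length(um)) stop(sprintf("unknown config key: 'mesh.%s'", um[1]))
  }
  atria <- experiment == "atria_suite"
  nx <- if (!is.null(mesh$nx)) as.integer(mesh$nx) else if (atria) 80L else 40L
  ny <- if (!is.null(mesh$ny)) as.integer(mesh$ny) else if (atria) 50L else 40L
  dx_cm <- if (!is.null(mesh$dx_cm)) mesh$dx_cm
    else if (!is.null(mesh$dx_mm)) mesh$dx_mm / 10
    else if (!is.null(mesh$dx_um)) mesh$dx_um * 1e-4
    else if (atria) 0.05 else 0.025
  if (!is.null(config$duration_ms) && !is.null(config$duration_s))
    stop("give duration_ms or duration_s, not both")
  duration_ms <- if (!is.null(config$duration_ms)) config$duration_ms
    else if (!is.null(config$duration_s)) config$duration_s * 1000
    else 20000
  radius_cm <- if (!is.null(config$patch_radius_cm)) config$patch_radius_cm
    else if (!is.null(config$patch_radius_mm)) config$patch_radius_mm / 10
    else if (atria) 0.5 else 0.5
  out <- list(
    experiment = experiment, nx = nx, ny = ny, dx_cm = dx_cm,
    duration_ms = duration_ms,
    intensities = if (is.null(config$intensities)) 0.5 else
      as.numeric(config$intensities),
    patch_radius_cm = radius_cm,
    target_fraction = if (is.null(config$target_fraction)) 0.5 else
      config$target_fraction,
    seeds = seeds,
    threshold_mv = if (is.null(config$threshold_mv)) 0 else config$threshold_mv,
    dt_reaction_ms = config$dt_reaction_ms,
    outdir = config$outdir)
  stopifnot(out$nx >= 1, out$ny >= 1, out$dx_cm > 0, out$duration_ms > 0,
            all(out$intensities > 0), all(out$intensities < 1),
            out$patch_radius_cm > 0, out$target_fraction > 0,
            out$target_fraction <= 1)
  structure(out, class = "cardiomod_config")
}

#' Run one hiPSC-CM remodeling scenario
#'
#' Builds a square hiPSC tissue, applies circular-patch remodeling for one
#' scenario row of [enumerate_hipsc_scenarios()], runs a spontaneous
#' recording and computes the tissue beat irregularity.
#'
#' @param scenario One row of [enumerate_hipsc_scenarios()] (or a
#'   compatible list with `name`, `s_na`, `s_nak`, `s_cond`).
#' @param seed Patch-placement seed.
#' @param nx,ny,dx_um Mesh geometry.
#' @param duration_ms Spontaneous recording length.
#' @param radius_cm,target_fraction Patch geometry (defaults: 0.5 cm
#'   patches covering half of the tissue).
#' @param base_diffusivity Control diffusivity; calibrated default if
#'   `NULL`.
#' @param dt_reaction Reaction time step (model default if `NULL`).
#' @return List: `irregularity` (an `irregularity_result`), `result`
#'   (the `simulation_result`), `map` (the `remodeling_map` or `NULL` for
#'   control).
#' @export
simulate_hipsc_scenario <- function(scenario, seed, nx = 40, ny = 40,
                                    dx_um = 250, duration_ms = 20000,
                                    radius_cm = 0.5, target_fraction = 0.5,
                                    base_diffusivity = NULL,
                                    dt_reaction = NULL) {
  grid <- build_square_tissue(nx, ny, dx_um, base_diffusivity, "hipsc")
  map <- NULL
  if (!identical(scenario$name, "control")) {
    map <- place_circular_patches(
      grid, radius_cm, target_fraction, "tissue", seed,
      scalers = c(s_na = scenario$s_na, s_nak = scenario$s_nak,
                  s_cond = scenario$s_cond))
    grid <- apply_remodeling(grid, map)
  }
  res <- run_tissue(grid, spontaneous_protocol(duration_ms),
                    dt_reaction = dt_reaction, seed = seed)
  # a quiescent tissue (e.g. remodeling-induced cessation of beating) has
  # no irregularity statistic; report NULL rather than failing the run
  irr <- tryCatch(tissue_irregularity(res$activation_map),
                  error = function(e) NULL)
  list(irregularity = irr, result = res, map = map)
}

.suite_row <- function(name, seed, status, irr = NA, rate = NA, het = NA,
                       cv = NA, af = NA, hash = NA) {
  data.frame(scenario = name, seed = seed, status = status,
             irregularity_pct = irr, mean_rate_bpm = rate,
             heterogeneity = het, cv_cm_s = cv, af_sustained = af,
             config_hash = hash, stringsAsFactors = FALSE)
}

.run_metrics <- function(res) {
  irr <- tryCatch(tissue_irregularity(res$activation_map),
                  error = function(e) NULL)
  fld <- tryCatch(conduction_field(res$activation_map, beat = 2),
                  error = function(e) NULL)
  het <- tryCatch(heterogeneity_index(fld), error = function(e) NA_real_)
  cv <- if (!is.null(fld) && any(fld$valid, na.rm = TRUE))
    stats::median(fld$speed_cm_s[fld$valid], na.rm = TRUE) else NA_real_
  list(irr = if (is.null(irr)) NA_real_ else irr$irregularity_pct,
       rate = if (is.null(irr)) NA_real_ else irr$mean_rate_bpm,
       het = het, cv = cv)
}

#' Run the full scenario suite described by a configuration
#'
#' Executes the control plus every enumerated remodeling scenario of the
#' configured experiment, writing one sub-directory per run (activation-map
#' CSV plus a JSON result record embedding the normalized run configuration
#' and its hash) and a `summary.csv` across runs. Completed runs are
#' detected by their configuration hash and skipped on re-execution.
#' Individual run failures are recorded (`status = "failed"`) and the suite
#' continues; the returned summary then carries `exit_status` 1 instead
#' of 0.
#'
#' @param config Path to a YAML config, a list, or a `cardiomod_config`.
#' @param outdir Results directory (created if missing); overrides the
#'   config's `outdir`.
#' @return The summary data frame, invisibly, with attributes
#'   `exit_status` and `outdir`.
#' @export
run_scenario_suite <- function(config, outdir = NULL) {
  cf <- if (inherits(config, "cardiomod_config")) config else parse_config(config)
  outdir <- outdir %||% cf$outdir %||% stop("no output directory configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (cf$experiment == "hipsc_suite") {
    sc <- enumerate_hipsc_scenarios(cf$intensities)
    runs <- do.call(rbind, lapply(seq_len(nrow(sc)), function(i) {
      seeds <- if (sc$name[i] == "control") cf$seeds[1] else cf$seeds
      data.frame(row = i, seed = seeds)
    }))
  } else {
    sc <- enumerate_atria_configs(radius_cm = cf$patch_radius_cm)
    runs <- do.call(rbind, lapply(seq_len(nrow(sc)), function(i) {
      seeds <- if (sc$name[i] == "control") cf$seeds[1] else cf$seeds
      data.frame(row = i, seed = seeds)
    }))
  }

  rows <- list()
  failed <- FALSE
  for (k in seq_len(nrow(runs))) {
    scen <- sc[runs$row[k], ]
    seed <- runs$seed[k]
    run_cfg <- c(unclass(cf), list(scenario = as.list(scen), seed = seed))
    hash <- config_hash(run_cfg)
    run_dir <- file.path(outdir, sprintf("%s_seed%d", scen$name, seed))
    marker <- file.path(run_dir, "result.json")
    if (file.exists(marker)) {
      prev <- jsonlite::read_json(marker)
      if (identical(prev$config_hash, hash)) {
        rows[[k]] <- .suite_row(scen$name, seed, "cached",
                                .num_or_na(prev$irregularity_pct),
                                .num_or_na(prev$mean_rate_bpm),
                                .num_or_na(prev$heterogeneity),
                                .num_or_na(prev$cv_cm_s),
                                .lgl_or_na(prev$af_sustained), hash)
        next
      }
    }
    dir.create(run_dir, showWarnings = FALSE)
    rows[[k]] <- tryCatch({
      if (cf$experiment == "hipsc_suite") {
        out <- simulate_hipsc_scenario(
          scen, seed, cf$nx, cf$ny, cf$dx_cm * 1e4, cf$duration_ms,
          cf$patch_radius_cm, cf$target_fraction,
          dt_reaction = cf$dt_reaction_ms)
        res <- out$result
        met <- .run_metrics(res)
        af <- NA
      } else {
        grid <- build_pseudo_atria(pseudo_atria_config(cf$nx, cf$ny,
                                                       cf$dx_cm * 1e4))
        map <- atria_remodeling(grid, scen$ra_mode, scen$la_mode, seed,
                                radius_cm = cf$patch_radius_cm)
        grid <- apply_remodeling(grid, map)
        proto <- stress_pacing_protocol()
        res <- run_tissue(grid, proto, seed = seed,
                          duration_ms = min(cf$duration_ms,
                                            proto$duration_ms),
                          dt_reaction = cf$dt_reaction_ms)
        # short (truncated) runs cannot assess sustained activity
        af <- tryCatch(
          detect_sustained_activity(res$activation_map,
                                    last_stimulus_time(proto))$sustained,
          error = function(e) NA)
        met <- .run_metrics(res)
      }
      write_activation_csv(res$activation_map,
                           file.path(run_dir, "activation.csv"))
      rec <- list(config_hash = hash, config = unclass_recursive(run_cfg),
                  irregularity_pct = met$irr, mean_rate_bpm = met$rate,
                  heterogeneity = met$het, cv_cm_s = met$cv,
                  af_sustained = af,
                  package_version = as.character(
                    utils::packageVersion("cardiomod")))
      jsonlite::write_json(rec, file.path(run_dir, "result.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
      .suite_row(scen$name, seed, "ok", met$irr, met$rate, met$het, met$cv,
                 af, hash)
    }, error = function(e) {
      failed <<- TRUE
      message(sprintf("scenario %s (seed %d) failed: %s", scen$name, seed,
                      conditionMessage(e)))
      .suite_row(scen$name, seed, "failed")
    })
  }
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  attr(summary, "exit_status") <- if (failed) 1L else 0L
  attr(summary, "outdir") <- outdir
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
.num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
.lgl_or_na <- function(x) if (is.null(x)) NA else as.logical(x)
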