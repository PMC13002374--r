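# Spatially heterogeneous inflammatory remodeling: circular patches carrying
# multiplicative downregulation of I_Na, I_NaK and tissue conductivity, and
# enumeration of the standard scenario grids.

#' Place non-overlapping circular remodeling patches
#'
#' Rejection sampling: candidate circle centers are drawn uniformly over the
#' target region; a candidate is accepted when its center keeps at least
#' one diameter from every accepted center (non-overlap) and the resulting
#' coverage does not overshoot the target band. Placement stops once the
#' achieved coverage is within `coverage_tol` of `target_fraction`. Patches
#' may overlap the region boundary; they are clipped to the region and the
#' clipped area is what counts towards coverage. Coverage is the exact
#' remodeled-element count divided by the region element count.
#'
#' @param grid A `tissue_grid`.
#' @param radius_cm Patch radius (cm); at least one element edge.
#' @param target_fraction Fraction of the region to remodel, in (0, 1].
#' @param region Region name (default `"tissue"`).
#' @param seed RNG seed (mandatory: placement is stochastic).
#' @param scalers Named numeric vector `c(s_na=, s_nak=, s_cond=)` applied
#'   inside patches, each in (0, 1].
#' @param coverage_tol Acceptable deviation from the target, in coverage
#'   fraction points (default 0.02).
#' @param max_attempts Placement attempts before giving up.
#' @return A `remodeling_map`: per-element scaler matrices (`s_na`,
#'   `s_nak`, `s_cond`, exactly 1 outside all patches), the source patch
#'   table, achieved `coverage`, and bookkeeping.
#' @export
place_circular_patches <- function(grid, radius_cm, target_fraction,
                                   region = "tissue", seed,
                                   scalers = c(s_na = 1, s_nak = 1, s_cond = 1),
                                   coverage_tol = 0.02,
                                   max_attempts = 10000) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for patch placement")
  if (!is.numeric(target_fraction) || target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  if (radius_cm < grid$dx_cm) stop("radius must be at least one element edge")
  for (nm in c("s_na", "s_nak", "s_cond")) {
    v <- scalers[[nm]]
    if (is.null(v) || v <= 0 || v > 1)
      stop(sprintf("scaler %s must lie in (0, 1]", nm))
  }
  mask <- grid$regions[[region]]
  if (is.null(mask)) stop(sprintf("unknown region '%s'", region))
  n_mask <- length(mask)
  nx <- grid$nx
  cx <- ((mask - 1L) %% nx + 0.5) * grid$dx_cm
  cy <- ((mask - 1L) %/% nx + 0.5) * grid$dx_cm

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  covered <- logical(n_mask)
  patches <- data.frame(cx_cm = numeric(0), cy_cm = numeric(0),
                        radius_cm = numeric(0))
  lo <- target_fraction - coverage_tol
  hi <- target_fraction + coverage_tol

  if (target_fraction >= 1) {
    covered[] <- TRUE
  } else {
    # rejection sampling with restarts: fixed-radius non-overlapping circles
    # jam easily just below the target band, so the attempt budget is spent
    # over several fresh layouts rather than one stuck one
    n_restarts <- 25L
    per_restart <- max(50L, max_attempts %/% n_restarts)
    best_cov <- -1
    best <- NULL
    for (restart in seq_len(n_restarts)) {
      covered <- logical(n_mask)
      patches <- patches[0, ]
      attempts <- 0L
      while (mean(covered) < lo && attempts < per_restart) {
        attempts <- attempts + 1L
        # uniform center within a random element of the region
        j <- sample.int(n_mask, 1L)
        px <- cx[j] + (stats::runif(1) - 0.5) * grid$dx_cm
        py <- cy[j] + (stats::runif(1) - 0.5) * grid$dx_cm
        if (nrow(patches) > 0 &&
            any((patches$cx_cm - px)^2 + (patches$cy_cm - py)^2 <
                (patches$radius_cm + radius_cm)^2)) next
        inside <- (cx - px)^2 + (cy - py)^2 <= radius_cm^2
        new_cov <- mean(covered | inside)
        if (new_cov > hi) next
        covered <- covered | inside
        patches[nrow(patches) + 1L, ] <- c(px, py, radius_cm)
      }
      if (mean(covered) > best_cov) {
        best_cov <- mean(covered)
        best <- list(covered = covered, patches = patches)
      }
      if (best_cov >= lo) break
    }
    covered <- best$covered
    patches <- best$patches
    if (mean(covered) < lo)
      stop(sprintf(
        "patch placement geometrically infeasible: best achieved coverage %.1f%% (target %.1f%% +/- %.1f pts)",
        100 * mean(covered), 100 * target_fraction, 100 * coverage_tol))
  }

  s_na <- matrix(1, grid$nx, grid$ny)
  s_nak <- matrix(1, grid$nx, grid$ny)
  s_cond <- matrix(1, grid$nx, grid$ny)
  el <- mask[covered]
  s_na[el] <- scalers[["s_na"]]
  s_nak[el] <- scalers[["s_nak"]]
  s_cond[el] <- scalers[["s_cond"]]

  structure(list(s_na = s_na, s_nak = s_nak, s_cond = s_cond,
                 patches = patches, coverage = mean(covered),
                 target_fraction = target_fraction, radius_cm = radius_cm,
                 region = region, seed = seed,
                 remodeled_elements = el, n_region = n_mask,
                 nx = grid$nx, ny = grid$ny),
            class = "remodeling_map")
}

#' @export
print.remodeling_map <- function(x, ...) {
  cat(sprintf(
    "remodeling map: %d patch(es) of %g cm radius in '%s', coverage %.1f%% (target %.0f%%)\n",
    nrow(x$patches), x$radius_cm, x$region, 100 * x$coverage,
    100 * x$target_fraction))
  sc <- c(x$s_na[x$remodeled_elements[1]], x$s_nak[x$remodeled_elements[1]],
          x$s_cond[x$remodeled_elements[1]])
  if (length(x$remodeled_elements) > 0)
    cat(sprintf("  patch scalers: s_na %g, s_nak %g, s_cond %g\n",
                sc[1], sc[2], sc[3]))
  invisible(x)
}

#' Combine remodeling maps over disjoint regions
#'
#' @param ... `remodeling_map` objects on the same grid shape.
#' @return A `remodeling_map` whose scalers are the elementwise products.
#' @export
combine_remodeling <- function(...) {
  maps <- list(...)
  stopifnot(length(maps) >= 1)
  out <- maps[[1]]
  for (m in maps[-1]) {
    stopifnot(inherits(m, "remodeling_map"),
              m$nx == out$nx, m$ny == out$ny)
    out$s_na <- out$s_na * m$s_na
    out$s_nak <- out$s_nak * m$s_nak
    out$s_cond <- out$s_cond * m$s_cond
    out$patches <- rbind(out$patches, m$patches)
    out$remodeled_elements <- sort(union(out$remodeled_elements,
                                         m$remodeled_elements))
    out$region <- paste(out$region, m$region, sep = "+")
    out$coverage <- NA_real_
  }
  out
}

#' Apply a remodeling map to a tissue grid
#'
#' Per element, diffusivity becomes `base x s_cond` and the I_Na / I_NaK
#' scalers are multiplied in. Applying a control (all-ones) map leaves the
#' grid unchanged.
#'
#' @param grid A `tissue_grid`.
#' @param map A `remodeling_map` of matching shape.
#' @return The remodeled `tissue_grid`.
#' @export
apply_remodeling <- function(grid, map) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(map, "remodeling_map"))
  if (map$nx != grid$nx || map$ny != grid$ny)
    stop("remodeling map shape does not match the grid")
  act <- grid$D > 0
  grid$D[act] <- grid$D[act] * map$s_cond[act]
  grid$s_na <- grid$s_na * map$s_na
  grid$s_nak <- grid$s_nak * map$s_nak
  grid
}

#' Enumerate the hiPSC-CM remodeling scenarios
#'
#' Control plus six electrophysiological variations per intensity: the
#' three individual downregulations (I_Na, I_NaK, conductivity) and the
#' three pairwise combinations, each at 25% and 50% reduction by default.
#'
#' @param intensities Fractions reduced (default `c(0.25, 0.5)`).
#' @return Data frame (stable order: control, then singles and pairs per
#'   intensity) with logical axis columns and the resulting scalers.
#' @export
enumerate_hipsc_scenarios <- function(intensities = c(0.25, 0.5)) {
  axes <- list(
    ina = c(TRUE, FALSE, FALSE), inak = c(FALSE, TRUE, FALSE),
    cond = c(FALSE, FALSE, TRUE), ina_inak = c(TRUE, TRUE, FALSE),
    ina_cond = c(TRUE, FALSE, TRUE), inak_cond = c(FALSE, TRUE, TRUE))
  rows <- list(data.frame(
    name = "control", intensity = 0, down_na = FALSE, down_nak = FALSE,
    down_cond = FALSE, s_na = 1, s_nak = 1, s_cond = 1))
  for (int in intensities) {
    for (nm in names(axes)) {
      ax <- axes[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s_%d", nm, round(100 * int)), intensity = int,
        down_na = ax[1], down_nak = ax[2], down_cond = ax[3],
        s_na = ifelse(ax[1], 1 - int, 1),
        s_nak = ifelse(ax[2], 1 - int, 1),
        s_cond = ifelse(ax[3], 1 - int, 1))
    }
  }
  do.call(rbind, rows)
}

#' Enumerate the pseudo-atria remodeling configurations
#'
#' The Cartesian product of {control, localized (venous), spread} for the
#' right and left atrium gives eight remodeled configurations plus the
#' all-control mesh (nine in total). Remodeled patches carry a 50%
#' downregulation of I_NaK and a 50% conductivity reduction, with 0.5 cm
#' patch radius.
#'
#' @param intensity Fraction reduced inside patches (default 0.5).
#' @param radius_cm Patch radius (default 0.5).
#' @return Data frame with `name`, `ra_mode`, `la_mode`, `s_nak`, `s_cond`,
#'   `radius_cm`; the control row first.
#' @export
enumerate_atria_configs <- function(intensity = 0.5, radius_cm = 0.5) {
  modes <- c("control", "localized", "spread")
  gr <- expand.grid(ra_mode = modes, la_mode = modes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctrl <- gr$ra_mode == "control" & gr$la_mode == "control"
  gr <- rbind(gr[ctrl, ], gr[!ctrl, ])
  gr$name <- ifelse(gr$ra_mode == "control" & gr$la_mode == "control",
                    "control",
                    paste0("ra_", gr$ra_mode, "-la_", gr$la_mode))
  gr$s_nak <- ifelse(gr$name == "control", 1, 1 - intensity)
  gr$s_cond <- ifelse(gr$name == "control", 1, 1 - intensity)
  gr$radius_cm <- radius_cm
  rownames(gr) <- NULL
  gr[, c("name", "ra_mode", "la_mode", "s_nak", "s_cond", "radius_cm")]
}

#' Remodeling map for one pseudo-atria configuration
#'
#' Builds the patch layout for a row of [enumerate_atria_configs()]:
#' `localized` places patches in the chamber's venous sub-zone (covering
#' about half of it), `spread` across the whole chamber (covering half).
#'
#' @param grid A pseudo-atria `tissue_grid` (see [build_pseudo_atria()]).
#' @param ra_mode,la_mode `"control"`, `"localized"` or `"spread"`.
#' @param seed RNG seed for patch placement.
#' @param intensity Fraction reduced for I_NaK and conductivity.
#' @param radius_cm Patch radius (cm).
#' @param target_fraction Coverage of the targeted mask (default 0.45).
#' @param coverage_tol Coverage tolerance (default 0.1; the venous band is
#'   narrower than a patch diameter, so clipped coverage is coarse-grained).
#' @return A `remodeling_map` (all-ones if both chambers are control).
#' @export
atria_remodeling <- function(grid, ra_mode = "control", la_mode = "control",
                             seed, intensity = 0.5, radius_cm = 0.5,
                             target_fraction = 0.45, coverage_tol = 0.1) {
  stopifnot(inherits(grid, "tissue_grid"))
  sc <- c(s_na = 1, s_nak = 1 - intensity, s_cond = 1 - intensity)
  maps <- list()
  sides <- list(c(ra_mode, "venous_ra", "RA"), c(la_mode, "venous_la", "LA"))
  k <- 0L
  for (s in sides) {
    k <- k + 1L
    mode <- s[1]
    if (mode == "control") next
    region <- if (mode == "localized") s[2] else s[3]
    maps[[length(maps) + 1L]] <-
      place_circular_patches(grid, radius_cm, target_fraction, region,
                             seed = seed + k, scalers = sc,
                             coverage_tol = coverage_tol)
  }
  if (length(maps) == 0) {
    one <- matrix(1, grid$nx, grid$ny)
    return(structure(list(s_na = one, s_nak = one, s_cond = one,
                          patches = data.frame(cx_cm = numeric(0),
                                               cy_cm = numeric(0),
                                               radius_cm = numeric(0)),
                          coverage = 0, target_fraction = 0,
                          radius_cm = radius_cm, region = "none",
                          seed = seed, remodeled_elements = integer(0),
                          n_region = 0, nx = grid$nx, ny = grid$ny),
                     class = "remodeling_map"))
  }
  do.call(combine_remodeling, maps)
}
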