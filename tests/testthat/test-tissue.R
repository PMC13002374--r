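# Monodomain solver: mesh construction, no-flux conservation, square-root
# diffusivity scaling of conduction velocity, determinism, and the
# pseudo-atria geometry.

test_that("square mesh area follows nx * ny * dx^2", {
  g <- build_square_tissue(100, 100, 250)
  expect_equal(g$area_cm2, 6.25)
  g1 <- build_square_tissue(1, 1, 250)
  expect_equal(g1$area_cm2, 0.025^2)
  g2 <- build_square_tissue(40, 40, 250)
  expect_equal(g2$area_cm2, 1.0)
  expect_error(build_square_tissue(0, 10), "positive")
  expect_error(build_square_tissue(10, 10, dx_um = -1), "positive")
})

test_that("diffusion preserves a uniform field to machine precision", {
  g <- build_square_tissue(12, 12, 250, model = "atrial")
  y <- matrix(cell_initial_state("atrial"), ncol = 1)
  y[1] <- -30
  out <- step_monodomain(g, y, n_steps = 50, reaction = FALSE)
  expect_equal(max(abs(out[1, ] - (-30))), 0)
})

test_that("no-flux diffusion conserves total voltage content", {
  g <- build_square_tissue(15, 15, 250, model = "atrial")
  st <- matrix(cell_initial_state("atrial"), nrow = 21,
               ncol = 225)
  st[1, ] <- -80
  st[1, 113] <- 20  # single depolarized element
  total0 <- sum(st[1, ]) * g$dx_cm^2
  out <- step_monodomain(g, st, n_steps = 200, reaction = FALSE)
  expect_equal(sum(out[1, ]) * g$dx_cm^2, total0, tolerance = 1e-12)
  # and it actually diffused
  expect_lt(max(out[1, ]), 19)
})

test_that("conduction velocity scales as the square root of diffusivity", {
  # measured on a 125 um cable so the narrow low-diffusivity wavefront is
  # spatially resolved (the law is a continuum property)
  d0 <- 1.2e-3
  cv1 <- measure_cable_cv("atrial", d0, n_elements = 360, dx_um = 125,
                          dt = 0.002)$cv_cm_s
  cv2 <- measure_cable_cv("atrial", 4 * d0, n_elements = 360, dx_um = 125,
                          dt = 0.002)$cv_cm_s
  expect_lt(abs(cv2 / cv1 - 2), 0.1)  # 2x within 5%
})

test_that("halving dx changes measured conduction velocity by < 10%", {
  d <- 2.321e-3
  cv_coarse <- measure_cable_cv("atrial", d, n_elements = 160,
                                dx_um = 250)$cv_cm_s
  cv_fine <- measure_cable_cv("atrial", d, n_elements = 320,
                              dx_um = 125, dt = 0.01)$cv_cm_s
  expect_lt(abs(cv_fine - cv_coarse) / cv_coarse, 0.10)
})

test_that("identical configuration gives bit-identical activation maps", {
  g <- build_square_tissue(10, 10, 250, model = "atrial")
  p <- one_pulse(10, 400)
  r1 <- run_tissue(g, p, seed = 5)
  r2 <- run_tissue(g, p, seed = 5)
  expect_identical(r1$activation_map$times, r2$activation_map$times)
  expect_identical(r1$meta$config_hash, r2$meta$config_hash)
})

test_that("CFL violations are rejected with the admissible step reported", {
  g <- build_square_tissue(10, 10, 250, model = "atrial")
  expect_error(
    run_tissue(g, one_pulse(10, 100), dt_reaction = 0.02,
               dt_diffusion = 0.2),
    "CFL")
  expect_error(
    run_tissue(g, one_pulse(10, 100), dt_reaction = 0.02,
               dt_diffusion = 0.03),
    "multiple")
})

test_that("zero-duration tissue run yields an empty activation map", {
  g <- build_square_tissue(6, 6, 250, model = "atrial")
  r <- run_tissue(g, one_pulse(10, 100), duration_ms = 0)
  expect_true(all(lengths(r$activation_map$times) == 0))
})

test_that("paced atrial strip captures one activation per pulse", {
  g <- build_square_tissue(40, 3, 250, model = "atrial")
  p <- stimulus_protocol(pacing_train(20, 400, 5, 2), duration_ms = 2100)
  r <- run_tissue(g, p)
  counts <- lengths(r$activation_map$times)
  expect_true(all(counts == 5))
})

test_that("pseudo-atria geometry has all labeled regions and is connected", {
  g <- small_atria()
  for (nm in c("RA", "LA", "venous_ra", "venous_la", "bridge",
               "pacing_site"))
    expect_gt(length(g$regions[[nm]]), 0)
  expect_true(cardiomod:::.grid_connected(g))
  # chambers only reachable through the bridge: septum is non-tissue
  expect_true(any(g$D < 0))
  expect_error(
    build_pseudo_atria(pseudo_atria_config(bridge_rows = 0)),
    "bridge")
})

test_that("paced pseudo-atria capture fully on every sinus beat", {
  g <- small_atria()
  p <- stimulus_protocol(pacing_train(20, 700, 2, 2), duration_ms = 1500)
  r <- run_tissue(g, p)
  counts <- lengths(r$activation_map$times)[g$regions$tissue]
  expect_true(all(counts == 2))
})
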