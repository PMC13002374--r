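# Circular-patch remodeling: coverage control, determinism, non-overlap,
# scenario enumeration, and application to grids.

test_that("half-coverage patch placement lands within two points of target", {
  g <- build_square_tissue(100, 100, 250)  # the 6.25 cm^2 reference mesh
  m <- place_circular_patches(g, radius_cm = 0.5, target_fraction = 0.5,
                              seed = 7)
  expect_gte(m$coverage, 0.48)
  expect_lte(m$coverage, 0.52)
  # reported coverage equals a brute-force recount from the patch table
  ix <- rep(seq_len(g$nx), times = g$ny)
  iy <- rep(seq_len(g$ny), each = g$nx)
  cx <- (ix - 0.5) * g$dx_cm
  cy <- (iy - 0.5) * g$dx_cm
  inside <- rep(FALSE, g$nx * g$ny)
  for (k in seq_len(nrow(m$patches)))
    inside <- inside | ((cx - m$patches$cx_cm[k])^2 +
                          (cy - m$patches$cy_cm[k])^2 <= 0.5^2)
  expect_identical(sort(m$remodeled_elements), which(inside))
  expect_equal(m$coverage, mean(inside))
  # scalers outside all patches are exactly 1
  expect_true(all(m$s_na[-m$remodeled_elements] == 1))
  expect_true(all(m$s_nak[-m$remodeled_elements] == 1))
  expect_true(all(m$s_cond[-m$remodeled_elements] == 1))
})

test_that("patch placement is deterministic under a fixed seed and needs one", {
  g <- build_square_tissue(40, 40, 250)
  m1 <- place_circular_patches(g, 0.2, 0.5, seed = 3,
                               scalers = c(s_na = 1, s_nak = 0.5,
                                           s_cond = 0.5))
  m2 <- place_circular_patches(g, 0.2, 0.5, seed = 3,
                               scalers = c(s_na = 1, s_nak = 0.5,
                                           s_cond = 0.5))
  expect_identical(m1$patches, m2$patches)
  expect_identical(m1$s_nak, m2$s_nak)
  expect_error(place_circular_patches(g, 0.2, 0.5), "seed")
})

test_that("patches never overlap pairwise", {
  g <- build_square_tissue(60, 60, 250)
  m <- place_circular_patches(g, 0.25, 0.5, seed = 11)
  p <- m$patches
  if (nrow(p) > 1) {
    dmin <- min(as.matrix(stats::dist(p[, c("cx_cm", "cy_cm")]))[
      upper.tri(diag(nrow(p)))])
    expect_gte(dmin, 2 * 0.25 - 1e-12)
  }
  expect_gt(nrow(p), 1)
})

test_that("full coverage remodels every element and zero control elements remain", {
  g <- build_square_tissue(20, 20, 250)
  m <- place_circular_patches(g, 0.2, 1.0, seed = 1,
                              scalers = c(s_na = 0.5, s_nak = 1, s_cond = 1))
  expect_identical(length(m$remodeled_elements), 400L)
  expect_true(all(m$s_na == 0.5))
})

test_that("infeasible placement fails and reports the best achieved coverage", {
  g <- build_square_tissue(10, 10, 250)  # 0.25 cm square
  expect_error(
    place_circular_patches(g, 0.12, 0.9, seed = 2, max_attempts = 50),
    "achieved coverage")
})

test_that("hiPSC scenario grid enumerates control + 6 variations per intensity", {
  sc <- enumerate_hipsc_scenarios()
  expect_identical(nrow(sc), 13L)  # control + 6 x 2 intensities
  for (int in c(0.25, 0.5))
    expect_identical(sum(sc$intensity == int), 6L)
  pairs <- sc[sc$down_na + sc$down_nak + sc$down_cond == 2 &
                sc$intensity == 0.5, ]
  expect_setequal(pairs$name, c("ina_inak_50", "ina_cond_50", "inak_cond_50"))
  ctrl <- sc[sc$name == "control", ]
  expect_identical(c(ctrl$s_na, ctrl$s_nak, ctrl$s_cond), c(1, 1, 1))
  # singles at 25% reduce exactly one scaler to 0.75
  s25 <- sc[sc$intensity == 0.25 &
              sc$down_na + sc$down_nak + sc$down_cond == 1, ]
  expect_identical(nrow(s25), 3L)
  expect_true(all(rowSums(cbind(s25$s_na, s25$s_nak, s25$s_cond) == 0.75) == 1))
})

test_that("pseudo-atria configurations count 8 remodeled plus control", {
  cf <- enumerate_atria_configs()
  expect_identical(nrow(cf), 9L)
  expect_identical(sum(cf$name == "control"), 1L)
  expect_identical(sum(cf$name != "control"), 8L)
  expect_true(all(cf$s_nak[cf$name != "control"] == 0.5))
  expect_true(all(cf$s_cond[cf$name != "control"] == 0.5))
  expect_true(all(cf$radius_cm == 0.5))
})

test_that("scenario tables survive a JSON round trip", {
  sc <- enumerate_hipsc_scenarios()
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(sc, tf, digits = NA)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back, sc)
  cf <- enumerate_atria_configs()
  jsonlite::write_json(cf, tf, digits = NA)
  expect_equal(jsonlite::read_json(tf, simplifyVector = TRUE), cf)
})

test_that("localized venous remodeling stays inside its chamber mask", {
  g <- small_atria()
  m <- atria_remodeling(g, ra_mode = "control", la_mode = "localized",
                        seed = 4)
  expect_true(all(m$remodeled_elements %in% g$regions$venous_la))
  m2 <- atria_remodeling(g, ra_mode = "spread", la_mode = "control",
                         seed = 4)
  expect_true(all(m2$remodeled_elements %in% g$regions$RA))
})

test_that("applying remodeling scales diffusivity and scalers; control is identity", {
  g <- build_square_tissue(20, 20, 250)
  ctrl_map <- atria_remodeling(g, "control", "control", seed = 1)
  g_same <- apply_remodeling(g, ctrl_map)
  expect_identical(g_same$D, g$D)
  expect_identical(g_same$s_nak, g$s_nak)
  m <- place_circular_patches(g, 0.2, 0.5, seed = 9,
                              scalers = c(s_na = 1, s_nak = 0.5,
                                          s_cond = 0.5))
  g2 <- apply_remodeling(g, m)
  inside <- m$remodeled_elements
  expect_true(all(g2$D[inside] == g$D[inside] * 0.5))
  expect_true(all(g2$D[-inside] == g$D[-inside]))
  expect_true(all(g2$s_nak[inside] == 0.5))
  # shape mismatch rejected
  g_small <- build_square_tissue(10, 10, 250)
  expect_error(apply_remodeling(g_small, m), "shape")
})
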