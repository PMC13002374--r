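# Synthetic-readout generators: determinism, ground-truth bookkeeping, and
# parameter recovery by the analysis statistics.

test_that("beat-series generator honors its mean rate and interval CV", {
  s0 <- gen_beat_series(10, mean_rate_bpm = 72, cv_pct = 0, seed = 1)
  expect_equal(unique(round(diff(s0$times), 9)), 60000 / 72)
  expect_equal(beat_irregularity(s0)$irregularity_pct, 0)
  s <- gen_beat_series(5000, mean_rate_bpm = 60, cv_pct = 15, seed = 31)
  irr <- beat_irregularity(s)$irregularity_pct
  expect_gt(irr, 13.5)
  expect_lt(irr, 16.5)
  expect_equal(mean(60000 / diff(s$times)) / 60, 1, tolerance = 0.05)
  expect_error(gen_beat_series(2, seed = 1), "n >= 3")
  expect_error(gen_beat_series(10, cv_pct = -2, seed = 1), "non-negative")
  expect_error(gen_beat_series(10, cv_pct = 5), "seed")
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_beat_series(50, 65, 20, seed = 7)
  b <- gen_beat_series(50, 65, 20, seed = 7)
  expect_identical(a$times, b$times)
  c <- gen_beat_series(50, 65, 20, seed = 8)
  expect_false(identical(a$times, c$times))
  m1 <- gen_activation_map("planar", jitter_sd_ms = 3, seed = 5)
  m2 <- gen_activation_map("planar", jitter_sd_ms = 3, seed = 5)
  expect_identical(m1$times, m2$times)
  v1 <- gen_vector_field(100, 2, seed = 3)
  v2 <- gen_vector_field(100, 2, seed = 3)
  expect_identical(v1$ux, v2$ux)
})

test_that("generators do not disturb the session RNG stream", {
  set.seed(1234)
  x1 <- runif(1)
  set.seed(1234)
  invisible(gen_beat_series(10, seed = 99, cv_pct = 10))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("jitter-free periodic maps give zero per-element irregularity", {
  m <- gen_activation_map("planar", nx = 6, ny = 6, n_beats = 8,
                          cycle_ms = 600)
  irr <- tissue_irregularity(m)
  expect_equal(irr$irregularity_pct, 0, tolerance = 1e-9)
})

test_that("focal geometry is more heterogeneous than planar", {
  pl <- gen_activation_map("planar", nx = 15, ny = 15, n_beats = 1)
  fo <- gen_activation_map("focal", nx = 15, ny = 15, n_beats = 1,
                           source = c(8, 8))
  h_pl <- heterogeneity_index(conduction_field(pl))
  h_fo <- heterogeneity_index(conduction_field(fo))
  expect_gt(h_fo, h_pl)
})

test_that("vector fields reach the circular-statistics limits", {
  # near-degenerate concentration: all angles essentially equal
  tight <- gen_vector_field(500, kappa = 1e4, seed = 12)
  expect_lt(heterogeneity_index(tight), 0.01)
  # uniform angles: heterogeneity tends to 1
  unif <- gen_vector_field(10000, kappa = 0, seed = 13)
  expect_gt(heterogeneity_index(unif), 0.97)
  expect_error(gen_vector_field(100, kappa = -1, seed = 1), "non-negative")
})

test_that("stylized AP trains carry their APD90 and amplitude ground truth", {
  tr <- gen_ap_trace(n_beats = 4, cycle_ms = 900, apd_ms = 310,
                     alternans_ratio = 1)
  m <- ap_metrics(tr)
  expect_equal(m$apd90_var_pct, 0, tolerance = 1e-6)
  expect_true(all(abs(m$beats$apd90_ms - 310) < 2))
  tr2 <- gen_ap_trace(n_beats = 4, cycle_ms = 900, apd_ms = 310,
                      amplitude_mv = 100)
  expect_true(all(abs(ap_metrics(tr2)$beats$amplitude_mv - 100) < 1))
  expect_error(gen_ap_trace(apd_ms = 900, cycle_ms = 800), "inconsistent|shorter")
})
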