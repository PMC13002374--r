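# Readout statistics: activation detection, the beat-irregularity
# statistic, conduction fields, the heterogeneity index, AP morphology and
# sustained-activity classification.

test_that("threshold crossings are detected with interpolation and refractoriness", {
  t <- seq(0, 10000, by = 1)
  v <- -20 + 50 * sin(2 * pi * t / 1000)  # 1 Hz around -20 mV
  ev <- detect_activations(v, threshold_mv = 0, times = t)
  expect_identical(length(ev), 10L)
  expect_identical(length(detect_activations(rep(-70, 1000))), 0L)
  expect_error(detect_activations(c(-1, 1, -1), times = c(0, 1, 3)),
               "uniform")
  # synthetic AP train: events recovered within one sample interval
  tr <- gen_ap_trace(n_beats = 6, cycle_ms = 800, apd_ms = 250, dt = 0.5)
  gt <- attr(tr, "ground_truth")
  ev2 <- detect_activations(tr, refractory_ms = 100)
  expect_identical(length(ev2), 6L)
  truth <- gt$onset_ms + (0:5) * gt$cycle_ms +
    gt$upstroke_ms * (0 - (-75)) / 100  # crossing of 0 mV on the upstroke
  expect_true(all(abs(ev2 - truth) <= 0.5))
})

test_that("beat irregularity implements SD(rate)/mean(rate) x 100", {
  expect_equal(beat_irregularity(seq(0, 9000, by = 750))$irregularity_pct, 0)
  # rates 60, 70, 80 bpm: sample SD 10, mean 70
  times <- cumsum(c(0, 60000 / 60, 60000 / 70, 60000 / 80))
  r <- beat_irregularity(times)
  expect_equal(r$irregularity_pct, 100 * 10 / 70, tolerance = 1e-12)
  expect_identical(r$n_beats, 4L)
  expect_error(beat_irregularity(c(0, 800)), "insufficient")
  # population-SD mode scales by sqrt((n-1)/n)
  rp <- beat_irregularity(times, sd_mode = "population")
  expect_equal(rp$irregularity_pct,
               r$irregularity_pct * sqrt(2 / 3), tolerance = 1e-12)
})

test_that("beat irregularity is scale invariant in the intervals", {
  s <- gen_beat_series(50, mean_rate_bpm = 70, cv_pct = 20, seed = 8)
  a <- beat_irregularity(s)$irregularity_pct
  b <- beat_irregularity(s$times * 3.7)$irregularity_pct
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("synthetic interval CV is recovered by the irregularity statistic", {
  s <- gen_beat_series(200, mean_rate_bpm = 60, cv_pct = 25, seed = 123)
  irr <- beat_irregularity(s)$irregularity_pct
  expect_gt(irr, 20)
  expect_lt(irr, 30)
})

test_that("tissue irregularity aggregates per-element statistics", {
  # identical periodic activations everywhere -> 0
  times <- rep(list(seq(100, 5100, by = 500)), 16)
  m <- activation_map(times, 4, 4, 0.025, 6000)
  expect_equal(tissue_irregularity(m)$irregularity_pct, 0)
  # single-element map equals the element-level statistic
  s <- gen_beat_series(20, 60, 15, seed = 2)
  m1 <- activation_map(list(s$times), 1, 1, 0.025, max(s$times) + 100)
  expect_equal(tissue_irregularity(m1)$irregularity_pct,
               beat_irregularity(s)$irregularity_pct)
  # half the elements regular, half at CV 20%: median lies between groups
  reg <- lapply(1:8, function(i) seq(0, 19000, by = 1000))
  irr <- lapply(1:8, function(i)
    gen_beat_series(20, 60, 20, seed = i)$times)
  m2 <- activation_map(c(reg, irr), 4, 4, 0.025, 25000)
  per <- vapply(c(reg, irr), function(tt)
    beat_irregularity(tt)$irregularity_pct, 0)
  res <- tissue_irregularity(m2)
  expect_gte(res$irregularity_pct, 0)
  expect_lte(res$irregularity_pct, max(per))
  expect_equal(res$irregularity_pct, stats::median(per))
  # elements with < 3 activations are excluded and counted
  m3 <- activation_map(c(reg, list(c(1, 2))), 3, 3, 0.025, 20000)
  expect_identical(tissue_irregularity(m3)$n_excluded, 1L)
  m4 <- activation_map(rep(list(numeric(0)), 4), 2, 2, 0.025, 100)
  expect_error(tissue_irregularity(m4), "excluded")
})

test_that("conduction field recovers a planar wave exactly", {
  amap <- gen_activation_map("planar", nx = 15, ny = 12, dx_cm = 0.025,
                             speed_cm_s = 45, n_beats = 1)
  fld <- conduction_field(amap)
  sp <- fld$speed_cm_s[2:14, 2:11]
  expect_true(all(abs(sp - 45) < 1e-9))
  expect_true(all(abs(fld$ux[fld$valid] - 1) < 1e-9))
  expect_true(all(abs(fld$uy[fld$valid]) < 1e-9))
})

test_that("a focal wave yields radial directions at the stated speed", {
  amap <- gen_activation_map("focal", nx = 21, ny = 21, dx_cm = 0.025,
                             speed_cm_s = 30, n_beats = 1,
                             source = c(11, 11))
  fld <- conduction_field(amap)
  # away from the source the speed is recovered within 5%
  far <- fld$valid
  far[8:14, 8:14] <- FALSE
  expect_true(all(abs(fld$speed_cm_s[far] - 30) / 30 < 0.05))
  # directions point away from the source
  ix <- rep(1:21, times = 21); iy <- rep(1:21, each = 21)
  rx <- (ix - 11); ry <- (iy - 11)
  rn <- sqrt(rx^2 + ry^2)
  ok <- which(far)
  dot <- fld$ux[ok] * (rx / rn)[ok] + fld$uy[ok] * (ry / rn)[ok]
  expect_true(all(dot > 0.97))
})

test_that("simultaneous activation marks every element invalid", {
  times <- rep(list(c(50)), 25)
  m <- activation_map(times, 5, 5, 0.025, 100)
  fld <- conduction_field(m)
  expect_false(any(fld$valid))
  expect_error(heterogeneity_index(fld), "valid")
})

test_that("heterogeneity index spans 0 (uniform) to 1 (balanced quadruple)", {
  u <- cbind(rep(1, 50), rep(0, 50))
  expect_equal(heterogeneity_index(u), 0)
  q <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
  expect_equal(heterogeneity_index(q), 1)
  expect_error(heterogeneity_index(cbind(1, 0)), "2 valid")
})

test_that("heterogeneity matches the von Mises closed form at kappa = 4", {
  fld <- gen_vector_field(1000, kappa = 4, seed = 99)
  expected <- attr(fld, "ground_truth")$expected_heterogeneity
  expect_equal(expected, 1 - besselI(4, 1) / besselI(4, 0), tolerance = 1e-12)
  expect_lt(abs(heterogeneity_index(fld) - expected), 0.03)
})

test_that("heterogeneity is invariant under global rotation", {
  fld <- gen_vector_field(500, kappa = 2, seed = 17)
  h0 <- heterogeneity_index(fld)
  th <- 1.1
  rot <- fld
  rot$ux <- cos(th) * fld$ux - sin(th) * fld$uy
  rot$uy <- sin(th) * fld$ux + cos(th) * fld$uy
  expect_equal(heterogeneity_index(rot), h0, tolerance = 1e-12)
})

test_that("planar conduction composed with the heterogeneity index gives 0", {
  amap <- gen_activation_map("planar", nx = 12, ny = 12, speed_cm_s = 45,
                             n_beats = 1)
  expect_lt(heterogeneity_index(conduction_field(amap)), 1e-9)
})

test_that("AP metrics: identical beats have zero variance; alternans is recovered", {
  tr <- gen_ap_trace(n_beats = 6, cycle_ms = 900, apd_ms = 280,
                     alternans_ratio = 1)
  m <- ap_metrics(tr)
  expect_equal(m$apd90_var_pct, 0, tolerance = 1e-6)
  expect_equal(m$auc90_var_pct, 0, tolerance = 1e-6)
  tr2 <- gen_ap_trace(n_beats = 8, cycle_ms = 1000, apd_ms = 220,
                      alternans_ratio = 1.3, dt = 0.25)
  m2 <- ap_metrics(tr2)
  apd <- m2$beats$apd90_ms
  ratio <- mean(apd[c(FALSE, TRUE)]) / mean(apd[c(TRUE, FALSE)])
  expect_lt(abs(ratio - 1.3), 0.02 * 1.3)
  expect_true(all(abs(apd - attr(tr2, "ground_truth")$apd90_ms[1:length(apd)]) < 2))
})

test_that("AP amplitude and diastolic potential are measured faithfully", {
  tr <- gen_ap_trace(n_beats = 5, cycle_ms = 800, apd_ms = 250,
                     amplitude_mv = 100, diastolic_mv = -78)
  m <- ap_metrics(tr)
  expect_true(all(abs(m$beats$amplitude_mv - 100) < 1))
  expect_true(all(abs(m$beats$mdp_mv - (-78)) < 0.5))
})

test_that("a triangular pulse has the APD90 and AUC90 given by geometry", {
  # two identical pulses: rise 2 ms to +25, linear fall over 100 ms to -75
  dt <- 0.05
  t <- seq(0, 600, by = dt)
  v <- rep(-75, length(t))
  for (t0 in c(100, 350)) {
    rise <- t >= t0 & t < t0 + 2
    v[rise] <- -75 + 100 * (t[rise] - t0) / 2
    fall <- t >= t0 + 2 & t < t0 + 102
    v[fall] <- 25 - 100 * (t[fall] - t0 - 2) / 100
  }
  tr <- data.frame(time_ms = t, v_m = v)
  m <- ap_metrics(tr, events = detect_activations(tr, refractory_ms = 50))
  # V90 level = peak - 0.9*amplitude = -65; crossing at 90 ms down the fall
  apd_expect <- 2 + 90  # upstroke + 90% of the fall (similar triangles)
  expect_true(all(abs(m$beats$apd90_ms - apd_expect) < 0.5))
  # area above the V90 level: fall triangle + rise sliver above -65 mV
  auc_expect <- 0.5 * (25 - (-65)) * (0.9 * 100) +
    0.5 * (25 - (-65)) * (2 * 0.9)
  expect_true(all(abs(m$beats$auc90_mv_ms - auc_expect) / auc_expect < 0.02))
})

test_that("sustained activity is classified from post-pacing activations", {
  # planar paced control: nothing after the last beat -> not sustained
  quiet <- gen_activation_map("planar", nx = 10, ny = 10, n_beats = 5,
                              cycle_ms = 400)
  gt <- attr(quiet, "ground_truth")
  quiet$duration_ms <- gt$last_paced_ms + 2500
  s <- detect_sustained_activity(quiet, gt$last_paced_ms)
  expect_false(s$sustained)
  # appended rotor-like re-activation for 2 s -> sustained
  busy <- gen_activation_map("reentry", nx = 10, ny = 10, n_beats = 5,
                             cycle_ms = 400, reentry_cycle_ms = 200,
                             reentry_duration_ms = 2200)
  gt2 <- attr(busy, "ground_truth")
  busy$duration_ms <- max(unlist(busy$times)) + 500
  s2 <- detect_sustained_activity(busy, gt2$last_paced_ms)
  expect_true(s2$sustained)
  expect_error(detect_sustained_activity(quiet, gt$last_paced_ms,
                                         window_ms = 0), "positive")
  expect_error(detect_sustained_activity(quiet, gt$last_paced_ms,
                                         window_ms = 1e6), "short")
})

test_that("activation maps survive a CSV round trip", {
  amap <- gen_activation_map("focal", nx = 6, ny = 5, n_beats = 3,
                             cycle_ms = 700, jitter_sd_ms = 2, seed = 5)
  tf <- tempfile(fileext = ".csv")
  write_activation_csv(amap, tf)
  back <- read_activation_csv(tf)
  expect_equal(back$times, amap$times, tolerance = 1e-8)
  expect_identical(back$nx, amap$nx)
  expect_equal(back$duration_ms, amap$duration_ms)
})
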