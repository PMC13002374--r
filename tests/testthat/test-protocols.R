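# Protocol construction and conductivity calibration.

test_that("spontaneous protocol defaults to a 50 s empty train", {
  p <- spontaneous_protocol()
  expect_identical(p$duration_ms, 50000)
  expect_identical(length(p$trains), 0L)
  p2 <- spontaneous_protocol(1000)
  expect_identical(p2$duration_ms, 1000)
  expect_error(spontaneous_protocol(-5), "positive")
  expect_error(spontaneous_protocol(0), "positive")
})

test_that("stress pacing composes 10 sinus + 5 tachycardia beats at 700/310 ms", {
  p <- stress_pacing_protocol(onset_ms = 50)
  expect_identical(length(p$trains), 2L)
  expect_identical(sum(vapply(p$trains, `[[`, 0L, "n_pulses")), 15L)
  expect_identical(p$trains[[1]]$cycle_length_ms, 700)
  expect_identical(p$trains[[2]]$cycle_length_ms, 310)
  # the stress train starts one 310 ms cycle after the 10th sinus pulse,
  # so its last pulse lands at onset + 9*700 + 5*310
  expect_identical(last_stimulus_time(p), 50 + 9 * 700 + 310 * 5)
})

test_that("ill-posed trains are rejected", {
  expect_error(pacing_train(0, 2, 5, pulse_ms = 2), "exceed")
  expect_error(
    stimulus_protocol(pacing_train(0, 100, 10, 2),
                      pacing_train(1, 100, 10, 2),
                      duration_ms = 2000),
    "overlapping")
})

test_that("calibration hits its target and survives an independent round trip", {
  cal <- calibrate_conductivity("atrial", target_cv_cm_s = 60,
                                n_elements = 160)
  again <- measure_cable_cv("atrial", cal$diffusivity, n_elements = 160)
  expect_true(again$valid)
  expect_lt(abs(again$cv_cm_s - 60) / 60, 0.02)
})

test_that("calibration is monotone: faster targets need more diffusivity", {
  lo <- calibrate_conductivity("atrial", target_cv_cm_s = 50,
                               n_elements = 160)
  hi <- calibrate_conductivity("atrial", target_cv_cm_s = 90,
                               n_elements = 160)
  expect_gt(hi$diffusivity, lo$diffusivity)
  # quadratic (sqrt-law) relation between target and diffusivity
  ratio <- hi$diffusivity / lo$diffusivity
  expect_lt(abs(ratio - (90 / 50)^2) / (90 / 50)^2, 0.25)
})

test_that("unreachable targets report the achievable range", {
  expect_error(
    calibrate_conductivity("atrial", target_cv_cm_s = 2000,
                           n_elements = 120),
    "achievable range")
})
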