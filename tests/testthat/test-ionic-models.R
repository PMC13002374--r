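# Single-cell electrophysiology: current scaling semantics, hallmark
# behaviors of the two models, integrator convergence, and agreement with
# an independent adaptive-step integration of the same equations.

test_that("current scalers act multiplicatively and exactly on their target currents", {
  for (model in cell_models()) {
    y <- cell_initial_state(model)
    y[1] <- 10  # depolarized: I_Na driving force and gates nonzero
    i0 <- ionic_rhs(y, model, current_scalers(s_na = 0))$i_ion
    i1 <- ionic_rhs(y, model, current_scalers(s_na = 1))$i_ion
    ih <- ionic_rhs(y, model, current_scalers(s_na = 0.5))$i_ion
    # linear in s_na: the I_Na term is exactly s_na * I_Na
    expect_equal(ih, i0 + 0.5 * (i1 - i0), tolerance = 1e-12)
    j0 <- ionic_rhs(y, model, current_scalers(s_nak = 0))$i_ion
    j1 <- ionic_rhs(y, model, current_scalers(s_nak = 1))$i_ion
    jh <- ionic_rhs(y, model, current_scalers(s_nak = 0.25))$i_ion
    expect_equal(jh, j0 + 0.25 * (j1 - j0), tolerance = 1e-12)
    expect_gt(abs(i1 - i0), 0)  # I_Na actually contributes at +10 mV
    expect_gt(abs(j1 - j0), 0)
  }
})

test_that("identity scalers reproduce the unscaled model and zero s_na removes I_Na", {
  y <- cell_initial_state("atrial")
  y[1] <- -20
  d_ctrl <- ionic_rhs(y, "atrial")$dstate
  d_one <- ionic_rhs(y, "atrial", current_scalers(1, 1))$dstate
  expect_identical(d_ctrl, d_one)
  # with s_na = 0 the voltage derivative no longer depends on the m gate
  y2 <- y
  y2["m"] <- 0.9
  dv_a <- ionic_rhs(y, "atrial", current_scalers(s_na = 0))$dstate[["v"]]
  dv_b <- ionic_rhs(y2, "atrial", current_scalers(s_na = 0))$dstate[["v"]]
  expect_equal(dv_a, dv_b, tolerance = 1e-12)
})

test_that("invalid states and scalers are rejected with informative errors", {
  y <- cell_initial_state("hipsc")
  y["Cai"] <- NaN
  expect_error(ionic_rhs(y, "hipsc"), "Cai")
  expect_error(current_scalers(s_na = 2.5), "\\[0, 2\\]")
  expect_error(current_scalers(s_nak = -0.1), "\\[0, 2\\]")
  expect_error(ionic_rhs(cell_initial_state("hipsc"), "nosuch"))
})

test_that("hiPSC model beats spontaneously over 50 s; atrial model is quiescent", {
  tr <- run_single_cell("hipsc", duration_ms = 50000, output_dt = 1)
  acts <- attr(tr, "activations")
  expect_gte(length(acts), 1)
  rate <- 60000 / mean(diff(acts))
  expect_gt(rate, 20)   # physiological spontaneous range for hiPSC-CMs
  expect_lt(rate, 80)
  tr2 <- run_single_cell("atrial", duration_ms = 10000, output_dt = 1)
  expect_identical(length(attr(tr2, "activations")), 0L)
  expect_lt(max(abs(diff(tail(tr2$v_m, 100)))), 0.01)  # settled at rest
})

test_that("zero duration returns an empty trace with the state unchanged", {
  y <- cell_initial_state("hipsc")
  tr <- run_single_cell("hipsc", duration_ms = 0, init = y)
  expect_identical(nrow(tr), 0L)
  expect_equal(attr(tr, "state"), as.numeric(y))
})

test_that("gating variables remain in [0,1] under random valid initial states", {
  set.seed(42)
  for (model in cell_models()) {
    info <- cell_initial_state(model)
    ng <- n_gates(model)
    for (rep in 1:5) {
      y <- info
      y[1] <- runif(1, -90, 20)
      y[2:(1 + ng)] <- runif(ng)
      tr <- run_single_cell(model, duration_ms = 500, init = y,
                            output_dt = 100)
      st <- attr(tr, "state")
      gates <- st[2:(1 + ng)]
      expect_true(all(gates >= 0 & gates <= 1))
      expect_true(all(is.finite(st)))
    }
  }
})

test_that("halving the time step changes a 10 s trace by < 0.5 mV RMS", {
  tr1 <- run_single_cell("hipsc", duration_ms = 10000, dt = 0.02,
                         output_dt = 1)
  tr2 <- run_single_cell("hipsc", duration_ms = 10000, dt = 0.01,
                         output_dt = 1)
  expect_lt(trace_rms(tr1, tr2), 0.5)
  p <- stimulus_protocol(pacing_train(50, 700, 12, 2), duration_ms = 10000)
  ta <- run_single_cell("atrial", protocol = p, dt = 0.02, output_dt = 1)
  tb <- run_single_cell("atrial", protocol = p, dt = 0.01, output_dt = 1)
  expect_lt(trace_rms(ta, tb), 0.5)
})

test_that("halving I_NaK depolarizes the maximum diastolic potential", {
  ctrl <- run_single_cell("hipsc", duration_ms = 15000, output_dt = 1)
  down <- run_single_cell("hipsc", scalers = current_scalers(s_nak = 0.5),
                          duration_ms = 15000, output_dt = 1)
  mdp <- function(tr) {
    m <- ap_metrics(tr[tr$time_ms > 5000, ])
    mean(m$beats$mdp_mv)
  }
  expect_gt(mdp(down), mdp(ctrl))  # less negative under pump downregulation
})

test_that("spontaneous rate matches an independent adaptive-step integration within 1%", {
  skip_if_not_installed("deSolve")
  dur <- 12000
  rhs_fun <- function(t, y, parms) {
    list(ionic_rhs(y, "hipsc")$dstate)
  }
  y0 <- as.numeric(cell_initial_state("hipsc"))
  sol <- deSolve::lsoda(y0, seq(0, dur, by = 1), rhs_fun, NULL,
                        rtol = 1e-6, atol = 1e-8)
  ref_acts <- detect_activations(sol[, 2], refractory_ms = 100,
                                 times = sol[, 1])
  acts <- attr(run_single_cell("hipsc", duration_ms = dur, output_dt = 1),
               "activations")
  expect_gte(length(ref_acts), 4)
  rate_ref <- 60000 / mean(diff(ref_acts))
  rate_pkg <- 60000 / mean(diff(acts))
  expect_lt(abs(rate_pkg - rate_ref) / rate_ref, 0.01)
})
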