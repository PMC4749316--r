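test_that("default simulation reaches a periodic steady state", {
  sim <- default_sim()
  expect_s3_class(sim, "airflow_sim")
  expect_true(sim$converged)
  expect_lt(abs(sim$net_tracheal_volume), 1e-5)
  # period recovered to the accuracy implied by the steady-state tolerance
  expect_equal(sim$duration, sim$params$T, tolerance = 1e-4)
})

test_that("a breath carries four resistance switches and two qT crossings", {
  sim <- default_sim()
  kinds <- table(sim$events$kind)
  expect_equal(unname(kinds[["q1_zero"]]), 2)
  expect_equal(unname(kinds[["q2_zero"]]), 2)
  # one interior downward crossing; the closing upward crossing is breath_end
  expect_equal(unname(kinds[["qT_zero"]]), 1)
  expect_equal(unname(kinds[["breath_end"]]), 1)
  # sequence: enter region 1, leave it, tracheal reversal, cross region 4
  interior <- sim$events$kind[sim$events$kind != "breath_end"]
  expect_equal(interior, c("q1_zero", "q1_zero", "qT_zero",
                           "q2_zero", "q2_zero"))
  expect_true(all(diff(sim$events$t) >= 0))
})

test_that("the converged breath is periodic in the state", {
  sim <- simulate_airflow(airflow_params(), dt = 1e-2, steady_tol = 1e-8)
  s <- sim$series
  expect_lt(abs(s$x1[1] - s$x1[nrow(s)]), 1e-6)
  expect_lt(abs(s$x2[1] - s$x2[nrow(s)]), 1e-6)
})

test_that("looser steady-state tolerance converges in no more breaths", {
  loose <- simulate_airflow(airflow_params(), dt = 1e-2, steady_tol = 1e-3)
  tight <- simulate_airflow(airflow_params(), dt = 1e-2, steady_tol = 1e-5)
  expect_true(loose$converged && tight$converged)
  expect_lte(loose$breaths, tight$breaths)
})

test_that("parabronchial flow is unidirectional for the duck parameters", {
  sim <- default_sim()
  expect_gte(min(sim$series$qT[sim$series$phase == "INSP"]), -1e-10)
  expect_gte(min(sim$series$qP), -1e-10)
  expect_gt(max(sim$series$qP), 0)
})

test_that("unforced breathing cannot complete a breath", {
  expect_error(simulate_airflow(airflow_params(P_amp = 0)),
               "P_amp|horizon|no .*crossing")
})

test_that("unforced dynamics decay monotonically to the rest state", {
  p <- airflow_params(P_amp = 0)
  tr <- simulate_fixed_step(p, dt = 1e-4, t_end = 2, x0 = c(0.1, 0.1))
  nrm <- sqrt(tr$x1^2 + tr$x2^2)
  expect_true(all(diff(nrm) <= 1e-12))
  # the slow mode drains the sacs on a multi-second time scale
  expect_lt(nrm[length(nrm)], 0.8 * nrm[1])
})

test_that("event-driven and fixed-step trajectories agree from rest", {
  p <- airflow_params()
  ev <- simulate_breath(c(0, 0), t0 = 0, regime = regime_from_region("1"),
                        p = p, dt = 1e-4)
  rk <- simulate_fixed_step(p, dt = 1e-4, t_end = min(3, ev$end_time))
  keep <- rk$t <= max(ev$series$t)
  x1i <- stats::approx(ev$series$t, ev$series$x1, xout = rk$t[keep],
                       ties = "ordered")$y
  x2i <- stats::approx(ev$series$t, ev$series$x2, xout = rk$t[keep],
                       ties = "ordered")$y
  expect_lt(max(abs(x1i - rk$x1[keep])), 1e-4)
  expect_lt(max(abs(x2i - rk$x2[keep])), 1e-4)
})

test_that("simulated series satisfies junction conservation throughout", {
  s <- default_sim()$series
  scale <- pmax(abs(s$q1), abs(s$q2), abs(s$qT), 1e-12)
  expect_lt(max(abs(s$qT + s$q2 - s$q1) / scale), 1e-10)
})

test_that("phase boundaries split the breath at tracheal-flow reversals", {
  sim <- default_sim()
  ph <- detect_phase_boundaries(sim)
  expect_equal(ph$phase, c("INSP", "EXP"))
  expect_equal(ph$start[1], 0)
  expect_equal(ph$end[2], sim$duration)
  expect_equal(ph$end[1], ph$start[2])
  # durations match the published duck timing
  expect_equal(ph$end[1] - ph$start[1], 1.4, tolerance = 0.02 / 1.4)
  expect_equal(ph$end[2] - ph$start[2], 1.6, tolerance = 0.02 / 1.6)
})

test_that("a tracheal-flow-free series yields an empty phase partition", {
  fake <- structure(list(
    series = data.frame(t = seq(0, 3, by = 0.1), qT = 0),
    events = data.frame(t = numeric(0), kind = character(0)),
    duration = 3), class = "airflow_sim")
  ph <- detect_phase_boundaries(fake)
  expect_equal(nrow(ph), 0)
})

test_that("borderline valving yields zero parabronchial flow", {
  sim <- simulate_airflow(borderline_params(), dt = 1e-3)
  expect_true(sim$converged)
  expect_lt(max(abs(sim$series$qP)), 1e-9)
  # but there is still tidal flow in and out of the sacs
  expect_gt(max(sim$series$qT), 1e-3)
})

test_that("the breath structure is robust across breathing frequencies", {
  for (T in c(1.5, 3, 6)) {
    sim <- simulate_airflow(airflow_params(T = T), dt = 1e-2)
    expect_true(sim$converged)
    expect_equal(sim$duration, T, tolerance = 1e-4)
    expect_gte(min(sim$series$qP), -1e-10)
  }
})

test_that("halving the sampling step leaves trajectory values unchanged", {
  # dt controls output sampling only; events and states are located exactly,
  # so coincident sample times must carry identical states
  p <- airflow_params()
  a <- simulate_airflow(p, dt = 2e-3)
  b <- simulate_airflow(p, dt = 1e-3)
  common <- intersect(round(a$series$t, 9), round(b$series$t, 9))
  ia <- match(common, round(a$series$t, 9))
  ib <- match(common, round(b$series$t, 9))
  expect_equal(a$series$x1[ia], b$series$x1[ib], tolerance = 1e-10)
  expect_equal(a$series$x2[ia], b$series$x2[ib], tolerance = 1e-10)
})

test_that("simulation object methods print, summarise and expose coefficients", {
  sim <- default_sim()
  expect_output(print(sim), "breath")
  sm <- summary(sim)
  expect_s3_class(sm, "summary.airflow_sim")
  expect_output(print(sm), "efficiency|Efficiency")
  co <- coef(sim)
  expect_equal(unname(co["R_T"]), 10)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(sim))
})
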