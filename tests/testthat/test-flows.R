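# generic oracle: solve the junction network for the flows from first
# principles (unknown junction pressure PJ, Ohm's law on each branch,
# conservation at the junction), independent of the closed-form expressions
oracle_flows <- function(x1, x2, R1, R2, p) {
  P1 <- x1 + p$P_atm
  P2 <- x2 + p$P_atm
  # (P_atm - PJ)/RT + (P2 - PJ)/R2 = (PJ - P1)/R1
  PJ <- (p$P_atm / p$R_T + P2 / R2 + P1 / R1) /
    (1 / p$R_T + 1 / R2 + 1 / R1)
  list(qT = (p$P_atm - PJ) / p$R_T,
       q1 = (PJ - P1) / R1,
       q2 = (P2 - PJ) / R2,
       qP = (P1 - P2) / p$R_P,
       PJ = PJ)
}

test_that("regime construction maps valve branches to phase-plane regions", {
  expect_equal(region_label(flow_regime("insp", "insp")), "1")
  expect_equal(region_label(flow_regime("exp", "insp")), "23")
  expect_equal(region_label(flow_regime("exp", "exp")), "4")
  # (insp, exp) cannot occur in the breath cycle and must be rejected
  expect_error(flow_regime("insp", "exp"), "unreachable|insp.*exp")
  expect_equal(region_label(regime_from_region("23")), "23")
  expect_error(regime_from_region("5"))
})

test_that("regime resistances follow the duck valve settings", {
  p <- airflow_params()
  expect_equal(unname(regime_resistances(regime_from_region("1"), p)),
               c(1, 100))
  expect_equal(unname(regime_resistances(regime_from_region("23"), p)),
               c(50, 100))
  expect_equal(unname(regime_resistances(regime_from_region("4"), p)),
               c(50, 5))
})

test_that("flows vanish at equilibrium and PJ sits at atmospheric pressure", {
  p <- airflow_params()
  for (reg in c("1", "23", "4")) {
    f <- compute_flows(0, 0, regime_from_region(reg), p)
    expect_equal(f$qT, 0)
    expect_equal(f$q1, 0)
    expect_equal(f$q2, 0)
    expect_equal(f$qP, 0)
    expect_equal(f$PJ, p$P_atm)
  }
})

test_that("closed-form flows match a first-principles junction solve", {
  p <- airflow_params()
  f <- compute_flows(-0.1, -0.05, regime_from_region("1"), p)
  o <- oracle_flows(-0.1, -0.05, 1, 100, p)
  # the oracle subtracts large absolute pressures, so allow for cancellation
  expect_equal(f$qT, o$qT, tolerance = 1e-8)
  expect_equal(f$q1, o$q1, tolerance = 1e-8)
  expect_equal(f$q2, o$q2, tolerance = 1e-6)
  expect_equal(f$qP, o$qP, tolerance = 1e-8)
  expect_equal(f$PJ, o$PJ, tolerance = 1e-12)
  # spot values for the region-1 duck resistances (Rbar = 1110)
  expect_equal(f$qT, 0.009054, tolerance = 1e-3)
  expect_equal(f$q1, 0.009459, tolerance = 1e-3)
  expect_equal(f$q2, 0.000405, tolerance = 1e-2)
  expect_equal(f$qP, -0.02)
})

test_that("junction conservation qT + q2 = q1 holds for random draws", {
  ps <- random_params(100, seed = 101)
  set.seed(202)
  for (p in ps) {
    x1 <- runif(100, -2, 2)
    x2 <- runif(100, -2, 2)
    for (reg in c("1", "23", "4")) {
      f <- compute_flows(x1, x2, regime_from_region(reg), p)
      scale <- pmax(abs(f$q1), abs(f$q2), abs(f$qT), 1e-12)
      expect_lt(max(abs(f$qT + f$q2 - f$q1) / scale), 1e-12)
    }
  }
})

test_that("state derivative is consistent with the compartment balance", {
  # C_i dx_i/dt = (flow into sac i) + C_i dP_ext/dt
  p <- airflow_params()
  set.seed(7)
  for (i in 1:20) {
    x <- runif(2, -1, 1)
    t <- runif(1, 0, p$T)
    for (reg in c("1", "23", "4")) {
      rg <- regime_from_region(reg)
      f <- compute_flows(x[1], x[2], rg, p)
      dx <- state_derivative(t, x, rg, p)
      C1 <- p$C1 / 1000  # L/cmH2O
      C2 <- p$C2 / 1000
      rate <- external_pressure_rate(t, p)
      expect_equal(dx[1], (f$q1 - f$qP) / C1 + rate, tolerance = 1e-10)
      expect_equal(dx[2], (f$qP - f$q2) / C2 + rate, tolerance = 1e-10)
    }
  }
})

test_that("state derivative vanishes at rest when the forcing is flat", {
  p <- airflow_params()
  expect_equal(state_derivative(0, c(0, 0), regime_from_region("1"), p),
               c(0, 0))
  # equal pressures mean no parabronchial contribution
  f <- compute_flows(0.3, 0.3, regime_from_region("23"), p)
  expect_equal(f$qP, 0)
})

test_that("airsac volumes reduce to resting volumes and scale with C", {
  p <- airflow_params(P_c = 1033.6, P_amp = 0)
  v <- airsac_volumes(0, 0, 0, p)
  expect_equal(v$V1, 105.6)
  expect_equal(v$V2, 103.6)

  # default forcing at t = 0: P_ext = P_atm - P_amp/2
  pd <- airflow_params()
  v0 <- airsac_volumes(0, 0, 0, pd)
  expect_equal(v0$V1, pd$V1_res + pd$C1 * 0.25)
  expect_equal(v0$V2, pd$V2_res + pd$C2 * 0.25)

  # rigid-sac limit: volume pinned at the resting volume
  pr <- airflow_params(C_tot = 1e-9)
  vr <- airsac_volumes(0.5, -0.5, 1, pr)
  expect_equal(vr$V1, pr$V1_res, tolerance = 1e-6)
  expect_equal(vr$V2, pr$V2_res, tolerance = 1e-6)

  expect_warning(airsac_volumes(-1e5, 0, 0, pd), "non-positive")
})

test_that("phase-plane classification matches direct flow-sign evaluation", {
  p <- airflow_params()
  c1 <- classify_region(-0.2, -0.1, p)
  expect_equal(c1$region, "1")
  expect_gt(compute_flows(-0.2, -0.1, regime_from_region("1"), p)$q1, 0)

  c4 <- classify_region(0.1, 0.2, p)
  expect_equal(c4$region, "4")
  expect_gt(compute_flows(0.1, 0.2, regime_from_region("4"), p)$q2, 0)

  # equilibrium tie-break: all flows zero classifies as region 1
  c0 <- classify_region(0, 0, p)
  expect_equal(c0$region, "1")
  expect_equal(unname(c0$signs[["qT"]]), 1)
})
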