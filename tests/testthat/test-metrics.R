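test_that("trapezoidal flow integrals behave on reference cases", {
  # exact on a constant flow
  fake <- structure(list(
    series = data.frame(t = seq(0, 2, by = 0.1), qT = 0.3)),
    class = "airflow_sim")
  expect_equal(integrate_flow(fake, "qT", "breath"), 0.6)

  sim <- default_sim()
  # steady state: net tracheal volume over the breath vanishes
  expect_lt(abs(integrate_flow(sim, "qT", "breath")), 1e-5)
  # phase integrals add up to the breath integral
  for (fl in c("qT", "qP", "q1", "q2")) {
    expect_equal(integrate_flow(sim, fl, "insp") +
                   integrate_flow(sim, fl, "exp"),
                 integrate_flow(sim, fl, "breath"), tolerance = 1e-9)
  }
})

test_that("duck breath metrics reproduce the published steady-state values", {
  m <- default_metrics()
  expect_equal(m$efficiency, 0.868, tolerance = 0.003 / 0.868)
  expect_equal(m$insp_valving_efficacy, 0.980, tolerance = 0.003 / 0.98)
  expect_equal(m$exp_valving_efficacy, 0.886, tolerance = 0.003 / 0.886)
  expect_equal(m$exp_valving_efficacy_alt, 0.81, tolerance = 0.01 / 0.81)
  expect_equal(m$tidal_volume, 36.0, tolerance = 0.3 / 36)
  expect_equal(m$parabronchial_volume, 31.3, tolerance = 0.3 / 31.3)
  expect_equal(m$ventilation_caudal, 21.5, tolerance = 0.3 / 21.5)
  expect_equal(m$ventilation_cranial, 16.3, tolerance = 0.3 / 16.3)
  expect_equal(m$caudal_ventilation_fraction, 0.569, tolerance = 0.005 / 0.569)
  expect_equal(m$ie_flow_ratio, 0.862, tolerance = 0.01 / 0.862)
  expect_equal(m$ie_time_ratio, 0.89, tolerance = 0.01 / 0.89)
  expect_equal(m$peak_V1, 235.4, tolerance = 1 / 235.4)
  expect_equal(m$peak_V2, 221.9, tolerance = 1 / 221.9)
  expect_output(print(m), "efficiency|Efficiency")
})

test_that("inspiration and expiration durations partition the period", {
  m <- default_metrics()
  p <- default_sim()$params
  # phases partition the simulated breath exactly ...
  expect_equal(m$T_i + m$T_e, default_sim()$duration, tolerance = 1e-12)
  # ... and the breath length matches the forcing period at convergence
  expect_equal(m$T_i + m$T_e, p$T, tolerance = 1e-4)
  expect_equal(m$T_i, 1.4, tolerance = 0.02 / 1.4)
  expect_equal(m$T_e, 1.6, tolerance = 0.02 / 1.6)
  expect_gt(m$T_e, m$T_i)   # expiration is slower for the duck parameters
})

test_that("metric definitions respect their analytic bounds", {
  for (m in list(default_metrics(), breath_metrics(insp_only_sim()),
                 breath_metrics(exp_only_sim()))) {
    expect_gte(m$efficiency, 0); expect_lte(m$efficiency, 1)
    expect_gte(m$insp_valving_efficacy, 0)
    expect_lte(m$insp_valving_efficacy, 1)
    expect_gte(m$exp_valving_efficacy, 0)
    expect_lte(m$exp_valving_efficacy, 1)
    expect_gte(m$exp_valving_efficacy_alt, 0)
    expect_lte(m$exp_valving_efficacy_alt, 1)
    expect_gt(m$T_i, 0); expect_gt(m$T_e, 0)
  }
  # with back-leak present the share-of-outflow definition is the stricter one
  m <- default_metrics()
  expect_lte(m$exp_valving_efficacy_alt, m$exp_valving_efficacy)
})

test_that("volume metrics are invariant to the baseline pressure", {
  # shifting P_c moves the airsac volume baseline but not flows or ranges
  a <- simulate_airflow(airflow_params(), dt = 1e-3)
  b <- simulate_airflow(airflow_params(P_c = 1038.6), dt = 1e-3)
  ma <- breath_metrics(a); mb <- breath_metrics(b)
  expect_equal(ma$efficiency, mb$efficiency, tolerance = 1e-9)
  expect_equal(ma$tidal_volume, mb$tidal_volume, tolerance = 1e-9)
  expect_equal(ma$ventilation_caudal, mb$ventilation_caudal,
               tolerance = 1e-9)
  expect_equal(ma$ie_time_ratio, mb$ie_time_ratio, tolerance = 1e-9)
})

test_that("whole-animal reporting doubles volumes and preserves ratios", {
  sim <- default_sim()
  both <- breath_metrics(sim, whole_animal = TRUE)
  one <- breath_metrics(sim, whole_animal = FALSE)
  expect_equal(both$tidal_volume, 2 * one$tidal_volume)
  expect_equal(both$parabronchial_volume, 2 * one$parabronchial_volume)
  expect_equal(both$ventilation_caudal, 2 * one$ventilation_caudal)
  expect_equal(both$efficiency, one$efficiency)
  expect_equal(both$ie_flow_ratio, one$ie_flow_ratio)
  expect_equal(both$caudal_ventilation_fraction,
               one$caudal_ventilation_fraction)
})

test_that("single-valve configurations match their published breath values", {
  ma <- breath_metrics(insp_only_sim())
  expect_equal(ma$efficiency, 0.471, tolerance = 0.005 / 0.471)
  expect_equal(ma$insp_valving_efficacy, 0.987, tolerance = 0.005 / 0.987)
  expect_equal(ma$tidal_volume, 38.1, tolerance = 0.3 / 38.1)
  expect_equal(ma$parabronchial_volume, 17.9, tolerance = 0.3 / 17.9)

  mb <- breath_metrics(exp_only_sim())
  expect_equal(mb$efficiency, 0.423, tolerance = 0.005 / 0.423)
  expect_equal(mb$insp_valving_efficacy, 0.486, tolerance = 0.005 / 0.486)
  expect_equal(mb$tidal_volume, 38.4, tolerance = 0.3 / 38.4)
  expect_equal(mb$parabronchial_volume, 16.2, tolerance = 0.3 / 16.2)
})

test_that("no-valving borderline breathing moves no air through the lung", {
  sim <- simulate_airflow(borderline_params(), dt = 1e-3)
  m <- breath_metrics(sim)
  expect_lt(abs(m$efficiency), 1e-8)
  expect_lt(abs(m$parabronchial_volume), 1e-5)
  expect_gt(m$tidal_volume, 1)   # the sacs still ventilate
})
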