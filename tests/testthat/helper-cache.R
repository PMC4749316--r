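# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

default_sim <- function() {
  cached("default_sim", function() simulate_airflow(airflow_params(),
                                                    dt = 1e-4))
}

default_metrics <- function() {
  cached("default_metrics", function() breath_metrics(default_sim()))
}

insp_only_sim <- function() {
  cached("insp_only_sim",
         function() simulate_airflow(single_valve_params("insp_only"),
                                     dt = 1e-4))
}

exp_only_sim <- function() {
  cached("exp_only_sim",
         function() simulate_airflow(single_valve_params("exp_only"),
                                     dt = 1e-4))
}

# a configuration on the borderline of the unidirectional-flow condition:
# gamma * R1 = R2 in both regimes, so qP should vanish identically
borderline_params <- function() {
  airflow_params(R1_insp = 3, R2_insp = 3, R1_exp = 3, R2_exp = 3,
                 gamma = 1)
}

# random positive parameter sets respecting the valve-direction invariants
# R1_exp >= R1_insp and R2_insp >= R2_exp
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r1i <- exp(runif(1, log(0.2), log(20)))
    r2e <- exp(runif(1, log(0.2), log(20)))
    airflow_params(
      R1_insp = r1i,
      R1_exp = r1i * exp(runif(1, 0, log(100))),
      R2_exp = r2e,
      R2_insp = r2e * exp(runif(1, 0, log(100))),
      R_T = exp(runif(1, log(0.5), log(30))),
      R_P = exp(runif(1, log(0.5), log(10))),
      gamma = exp(runif(1, log(0.2), log(5))),
      C_tot = exp(runif(1, log(50), log(2000)))
    )
  })
}
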