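#' Single-valve reference configurations
#'
#' Two named configurations used to contrast the effect of a single
#' aerodynamic valve, both with \code{R1_insp = R2_exp = 3} cmH2O/(L/s),
#' equal compliances (\code{gamma = 1}) and \code{C_tot = 450} mL/cmH2O:
#' \describe{
#'   \item{\code{"insp_only"}}{effective inspiratory valving only:
#'     \code{R2_insp = 100 * R1_insp}, \code{R1_exp = R1_insp} (so
#'     \code{gamma * R1 = R2} holds with equality during expiration).}
#'   \item{\code{"exp_only"}}{effective expiratory valving only:
#'     \code{R2_insp = R2_exp}, \code{R1_exp = 20 * R2_exp} (so
#'     \code{gamma * R1 = R2} holds with equality during inspiration).}
#' }
#' All remaining parameters keep their defaults.
#'
#' @param which \code{"insp_only"} or \code{"exp_only"}.
#' @return An \code{\link{airflow_params}} object.
#' @export
single_valve_params <- function(which = c("insp_only", "exp_only")) {
  which <- match.arg(which)
  if (which == "insp_only")
    airflow_params(R1_insp = 3, R2_exp = 3, gamma = 1, C_tot = 450,
                   R2_insp = 300, R1_exp = 3)
  else
    airflow_params(R1_insp = 3, R2_exp = 3, gamma = 1, C_tot = 450,
                   R2_insp = 3, R1_exp = 60)
}

.sweep_metrics <- function(p, dt, steady_tol, max_breaths, whole_animal) {
  sim <- simulate_airflow(p, dt = dt, steady_tol = steady_tol,
                          max_breaths = max_breaths)
  m <- breath_metrics(sim, whole_animal = whole_animal)
  cert <- unidirectional_flow_condition(p)
  data.frame(converged = sim$converged, breaths = sim$breaths,
             verdict = cert$verdict, min_qP = min(sim$series$qP),
             peak_qP = max(sim$series$qP),
             m[c("tidal_volume", "parabronchial_volume", "efficiency",
                 "insp_valving_efficacy", "exp_valving_efficacy",
                 "exp_valving_efficacy_alt", "ie_flow_ratio",
                 "T_i", "T_e", "ie_time_ratio", "ventilation_caudal",
                 "ventilation_cranial", "caudal_ventilation_fraction")])
}

#' Sweep one model parameter
#'
#' Simulates the model to steady state for each value of a swept parameter
#' and tabulates the breath metrics.  Every point re-resolves all linked
#' parameters (\code{R_T}, \code{C1}, \code{C2}, and, unless overridden, the
#' valving resistances via the multipliers \code{k_insp} and \code{k_exp})
#' from the base configuration, so linkage constraints cannot drift across
#' the sweep.
#'
#' @param param name of the \code{\link{airflow_params}} argument to sweep
#'   (e.g. \code{"gamma"}, \code{"P_amp"}, \code{"T"}, \code{"C_tot"}).
#' @param values numeric vector of values.
#' @param base named list of \code{airflow_params} arguments held at every
#'   point (raw configuration, not a resolved object).
#' @param dt,steady_tol,max_breaths passed to \code{\link{simulate_airflow}}.
#' @param whole_animal passed to \code{\link{breath_metrics}}.
#' @return A data frame with one row per point: the swept value, the resolved
#'   key resistances/compliances, a convergence flag, the unidirectionality
#'   verdict, and all breath metrics.  Points whose certificate is not
#'   \code{"unidirectional"} are still simulated and flagged by the
#'   \code{verdict} column.
#' @export
run_sweep <- function(param, values, base = list(), dt = 1e-3,
                      steady_tol = 1e-5, max_breaths = 200,
                      whole_animal = TRUE) {
  stopifnot(is.character(param), length(param) == 1L)
  rows <- lapply(values, function(v) {
    args <- base
    args[[param]] <- v
    p <- do.call(airflow_params, args)
    cbind(data.frame(value = v, R1_insp = p$R1_insp, R2_insp = p$R2_insp,
                     R1_exp = p$R1_exp, R2_exp = p$R2_exp, gamma = p$gamma,
                     C_tot = p$C_tot, P_amp = p$P_amp, T = p$T),
          .sweep_metrics(p, dt, steady_tol, max_breaths, whole_animal))
  })
  res <- do.call(rbind, rows)
  names(res)[1] <- param
  res
}

#' Sweep the resistance ratio at constant total resistance
#'
#' Varies the ratio \code{r = R1_insp / R2_exp} while holding the total
#' \code{R1_insp + R2_exp} fixed (default 6 cmH2O/(L/s)), so the overall
#' resistance of the system does not change.  At each point the valving
#' strength is preserved by re-deriving \code{R2_insp = k_insp * R1_insp}
#' and \code{R1_exp = k_exp * R2_exp}.
#'
#' @param ratios positive numeric vector of \code{R1_insp / R2_exp} values.
#' @param total the constant sum \code{R1_insp + R2_exp} (cmH2O/(L/s)).
#' @inheritParams run_sweep
#' @return A data frame as in \code{\link{run_sweep}}, with the swept column
#'   named \code{ratio}.
#' @export
resistance_ratio_sweep <- function(ratios, total = 6, base = list(),
                                   dt = 1e-3, steady_tol = 1e-5,
                                   max_breaths = 200, whole_animal = TRUE) {
  stopifnot(all(ratios > 0), total > 0)
  rows <- lapply(ratios, function(r) {
    args <- base
    args$R1_insp <- total * r / (1 + r)
    args$R2_exp <- total / (1 + r)
    p <- do.call(airflow_params, args)
    cbind(data.frame(ratio = r, R1_insp = p$R1_insp, R2_insp = p$R2_insp,
                     R1_exp = p$R1_exp, R2_exp = p$R2_exp, gamma = p$gamma,
                     C_tot = p$C_tot, P_amp = p$P_amp, T = p$T),
          .sweep_metrics(p, dt, steady_tol, max_breaths, whole_animal))
  })
  do.call(rbind, rows)
}

#' Calibrate the compliance ratio to a target ventilation split
#'
#' Finds the compliance ratio \code{gamma = C1/C2} at which the simulated
#' caudal share of the total airsac ventilation equals a target fraction, at
#' fixed total compliance.  The caudal fraction is monotone increasing in
#' \code{gamma}, so the root is bracketed by a coarse scan and refined by
#' bisection on the simulated fraction.
#'
#' @param target_fraction target caudal ventilation fraction, in (0, 1).
#' @param C_tot total airsac compliance held fixed (mL/cmH2O).
#' @param base named list of further \code{\link{airflow_params}} arguments.
#' @param interval search interval for \code{gamma}.
#' @param tol tolerance on the achieved fraction.
#' @param dt,steady_tol,max_breaths passed to \code{\link{simulate_airflow}}.
#' @return The fitted \code{gamma}, with the achieved fraction and the number
#'   of simulations as attributes.
#' @examples
#' \donttest{
#' # the duck ventilation split of 56.9% caudal requires gamma ~ 1.35
#' fit_gamma_to_ventilation_fraction(0.569, C_tot = 450)
#' }
#' @export
fit_gamma_to_ventilation_fraction <- function(target_fraction, C_tot = 450,
                                              base = list(),
                                              interval = c(0.05, 20),
                                              tol = 1e-3, dt = 1e-3,
                                              steady_tol = 1e-5,
                                              max_breaths = 200) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  n_sim <- 0L
  frac <- function(g) {
    args <- base
    args$C_tot <- C_tot
    args$gamma <- g
    p <- do.call(airflow_params, args)
    sim <- simulate_airflow(p, dt = dt, steady_tol = steady_tol,
                            max_breaths = max_breaths)
    n_sim <<- n_sim + 1L
    breath_metrics(sim)$caudal_ventilation_fraction
  }
  # bracket by coarse geometric scan (the fraction is monotone in gamma)
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 9))
  fg <- vapply(grid, frac, numeric(1)) - target_fraction
  i <- which(fg[-length(fg)] <= 0 & fg[-1] >= 0)[1]
  if (is.na(i))
    stop("no gamma in [", interval[1], ", ", interval[2],
         "] achieves a caudal ventilation fraction of ", target_fraction,
         call. = FALSE)
  lo <- grid[i]; hi <- grid[i + 1]
  flo <- fg[i]; fhi <- fg[i + 1]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- frac(mid) - target_fraction
    if (abs(fm) < tol) {
      return(structure(mid, achieved_fraction = fm + target_fraction,
                       n_simulations = n_sim))
    }
    if (fm < 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  structure((lo + hi) / 2,
            achieved_fraction = frac((lo + hi) / 2),
            n_simulations = n_sim)
}
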