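#' Model parameters for the avian airflow model
#'
#' Builds a fully resolved, validated parameter set for the two-compartment
#' switched-resistance model of airflow through the avian respiratory system.
#' Unspecified values default to the duck parameter set used throughout the
#' package.  Linked quantities are derived from their parents unless given
#' explicitly:
#' \itemize{
#'   \item \code{R_T = 2 * R_trachea + R_EPPB} (the single-side reduction of
#'     the symmetric two-sided airway tree),
#'   \item \code{C1 = gamma * C_tot / (1 + gamma)},
#'     \code{C2 = C_tot / (1 + gamma)} where \code{gamma = C1/C2},
#'   \item \code{R2_insp = k_insp * R1_insp} (inspiratory valving strength),
#'   \item \code{R1_exp = k_exp * R2_exp} (expiratory valving strength).
#' }
#' Explicitly supplied derived values override the linkage; supplying both a
#' derived value and its parents is an error when they disagree (relative
#' tolerance \code{1e-9}).
#'
#' Units follow field convention: resistances in cmH2O/(L/s), compliances in
#' mL/cmH2O, volumes in mL, pressures in cmH2O, time in s.  All internal
#' computation converts to the consistent set \{cmH2O, L, s\}.
#'
#' @param P_atm atmospheric pressure (cmH2O).
#' @param R_trachea tracheal resistance (cmH2O/(L/s)).
#' @param R_EPPB resistance of the extrapulmonary primary bronchus, including
#'   the segmentum accelerans (cmH2O/(L/s)).
#' @param R_T effective tracheal + primary bronchus resistance of the reduced
#'   single-side model; derived from \code{R_trachea} and \code{R_EPPB} when
#'   \code{NULL}.
#' @param R_P dorsobronchial and parabronchial resistance (cmH2O/(L/s)).
#' @param R1_insp mesobronchus resistance during inspiration (flow towards the
#'   caudal airsacs).
#' @param R2_exp ventrobronchial resistance during expiration (flow out of the
#'   cranial airsacs).
#' @param R2_insp effective ventrobronchial resistance during inspiration
#'   (inspiratory valve); derived as \code{k_insp * R1_insp} when \code{NULL}.
#' @param R1_exp effective mesobronchus resistance during expiration
#'   (expiratory valve); derived as \code{k_exp * R2_exp} when \code{NULL}.
#' @param k_insp,k_exp dimensionless valving multipliers used to derive
#'   \code{R2_insp} and \code{R1_exp}.
#' @param gamma ratio of caudal to cranial airsac compliance, \code{C1/C2}.
#' @param C_tot total airsac compliance \code{C1 + C2} (mL/cmH2O).
#' @param C1,C2 caudal / cranial airsac compliances (mL/cmH2O); derived from
#'   \code{C_tot} and \code{gamma} when \code{NULL}.
#' @param V1_res,V2_res resting volumes of the caudal / cranial airsacs at
#'   zero transmural pressure, single side (mL).
#' @param P_c baseline coelomic (thoracic-abdominal) pressure (cmH2O).
#' @param P_amp peak-to-peak amplitude of the breathing pressure oscillation
#'   (cmH2O).
#' @param T respiratory period (s).
#'
#' @return An object of class \code{"airflow_params"}: a named list with all
#'   of the above fields resolved and validated.
#' @examples
#' p <- airflow_params()
#' p$R_T          # 10 = 2*1 + 8
#' p$C1           # 258.51... = 1.35 * 450 / 2.35
#' airflow_params(gamma = 1)$C1  # 225
#' @export
airflow_params <- function(P_atm = 1033.6,
                           R_trachea = 1, R_EPPB = 8, R_T = NULL,
                           R_P = 2.5,
                           R1_insp = 1, R2_exp = 5,
                           R2_insp = NULL, R1_exp = NULL,
                           k_insp = 100, k_exp = 10,
                           gamma = 1.35, C_tot = 450,
                           C1 = NULL, C2 = NULL,
                           V1_res = 105.6, V2_res = 103.6,
                           P_c = 1033.6, P_amp = 0.5, T = 3) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  rel_eq <- function(a, b, tol = 1e-9) abs(a - b) <= tol * max(abs(a), abs(b), 1)

  for (nm in c("P_atm", "R_trachea", "R_EPPB", "R_P", "R1_insp", "R2_exp",
               "k_insp", "k_exp", "T", "P_c", "V1_res", "V2_res"))
    chk_pos(get(nm), nm)
  if (!is.numeric(P_amp) || length(P_amp) != 1L || !is.finite(P_amp) || P_amp < 0)
    stop("'P_amp' must be a single non-negative finite number", call. = FALSE)

  # tracheal resistance linkage
  if (is.null(R_T)) {
    R_T <- 2 * R_trachea + R_EPPB
  } else {
    chk_pos(R_T, "R_T")
  }

  # compliance linkage: either (C_tot, gamma) or explicit (C1, C2)
  if (is.null(C1) != is.null(C2))
    stop("supply both 'C1' and 'C2' or neither", call. = FALSE)
  if (!is.null(C1)) {
    chk_pos(C1, "C1"); chk_pos(C2, "C2")
    if (!rel_eq(C1 + C2, C_tot))
      stop("inconsistent compliances: C1 + C2 = ", C1 + C2,
           " but C_tot = ", C_tot, call. = FALSE)
    if (!rel_eq(C1 / C2, gamma))
      stop("inconsistent compliances: C1/C2 = ", C1 / C2,
           " but gamma = ", gamma, call. = FALSE)
    C_tot <- C1 + C2
    gamma <- C1 / C2
  } else {
    chk_pos(C_tot, "C_tot"); chk_pos(gamma, "gamma")
    C1 <- gamma * C_tot / (1 + gamma)
    C2 <- C_tot / (1 + gamma)
  }

  # valving linkage
  if (is.null(R2_insp)) R2_insp <- k_insp * R1_insp else chk_pos(R2_insp, "R2_insp")
  if (is.null(R1_exp)) R1_exp <- k_exp * R2_exp else chk_pos(R1_exp, "R1_exp")
  k_insp <- R2_insp / R1_insp
  k_exp <- R1_exp / R2_exp

  if (R2_insp < R2_exp)
    stop("R2_insp (", R2_insp, ") must be >= R2_exp (", R2_exp,
         "): the inspiratory valve raises the ventrobronchial resistance",
         call. = FALSE)
  if (R1_exp < R1_insp)
    stop("R1_exp (", R1_exp, ") must be >= R1_insp (", R1_insp,
         "): the expiratory valve raises the mesobronchial resistance",
         call. = FALSE)

  structure(list(
    P_atm = P_atm, R_trachea = R_trachea, R_EPPB = R_EPPB, R_T = R_T,
    R_P = R_P, R1_insp = R1_insp, R2_insp = R2_insp,
    R1_exp = R1_exp, R2_exp = R2_exp, k_insp = k_insp, k_exp = k_exp,
    gamma = gamma, C_tot = C_tot, C1 = C1, C2 = C2,
    V1_res = V1_res, V2_res = V2_res,
    P_c = P_c, P_amp = P_amp, T = T
  ), class = "airflow_params")
}

#' @export
print.airflow_params <- function(x, ...) {
  cat("Avian airflow model parameters\n")
  cat(sprintf("  Resistances (cmH2O/(L/s)): R_T = %g (= 2*%g + %g), R_P = %g\n",
              x$R_T, x$R_trachea, x$R_EPPB, x$R_P))
  cat(sprintf("    R1: insp %g / exp %g   R2: insp %g / exp %g\n",
              x$R1_insp, x$R1_exp, x$R2_insp, x$R2_exp))
  cat(sprintf("  Compliances (mL/cmH2O): C1 = %.4g, C2 = %.4g (gamma = %.4g, C_tot = %g)\n",
              x$C1, x$C2, x$gamma, x$C_tot))
  cat(sprintf("  Resting volumes (mL): V1_res = %g, V2_res = %g\n",
              x$V1_res, x$V2_res))
  cat(sprintf("  Forcing: P_c = %g, P_amp = %g cmH2O (peak-to-peak), T = %g s\n",
              x$P_c, x$P_amp, x$T))
  invisible(x)
}

# internal: copy with compliances in L/cmH2O and volumes in L
.consistent <- function(p) {
  p$C1 <- p$C1 / 1000
  p$C2 <- p$C2 / 1000
  p$C_tot <- p$C_tot / 1000
  p$V1_res <- p$V1_res / 1000
  p$V2_res <- p$V2_res / 1000
  p
}

as_airflow_params <- function(p) {
  if (inherits(p, "airflow_params")) p else do.call(airflow_params, p)
}
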