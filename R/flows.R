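#' Flow regimes of the switched-resistance model
#'
#' The mesobronchial resistance \code{R1} and the ventrobronchial resistance
#' \code{R2} are discontinuous in the flow direction: \code{R1 = R1_insp} while
#' \code{q1 > 0} and \code{R1 = R1_exp} while \code{q1 < 0}; \code{R2 = R2_exp}
#' while \code{q2 > 0} and \code{R2 = R2_insp} while \code{q2 < 0}.  A regime
#' fixes one branch of each resistance.  Three regimes are reachable over a
#' breath; they correspond to the regions of the phase plane:
#' region 1 = (insp, insp), regions 2/3 = (exp, insp), region 4 = (exp, exp).
#' The combination (insp, exp) never occurs along the breath event sequence
#' and is rejected.
#'
#' @param r1_branch branch of R1, \code{"insp"} or \code{"exp"}.
#' @param r2_branch branch of R2, \code{"insp"} or \code{"exp"}.
#' @return An object of class \code{"flow_regime"}.
#' @examples
#' flow_regime("insp", "insp")   # region 1
#' regime_from_region("4")
#' @export
flow_regime <- function(r1_branch = c("insp", "exp"),
                        r2_branch = c("insp", "exp")) {
  r1_branch <- match.arg(r1_branch)
  r2_branch <- match.arg(r2_branch)
  if (r1_branch == "insp" && r2_branch == "exp")
    stop("the regime (R1 inspiratory, R2 expiratory) is unreachable: ",
         "q1 > 0 and q2 > 0 cannot hold simultaneously along a breath",
         call. = FALSE)
  structure(list(r1_branch = r1_branch, r2_branch = r2_branch),
            class = "flow_regime")
}

#' @rdname flow_regime
#' @param region region label, one of \code{"1"}, \code{"23"}, \code{"4"}.
#' @export
regime_from_region <- function(region) {
  switch(as.character(region),
         "1" = flow_regime("insp", "insp"),
         "2" = , "3" = , "23" = flow_regime("exp", "insp"),
         "4" = flow_regime("exp", "exp"),
         stop("unknown region label: ", region, call. = FALSE))
}

#' @rdname flow_regime
#' @param regime a \code{"flow_regime"} object.
#' @export
region_label <- function(regime) {
  if (regime$r1_branch == "insp") "1"
  else if (regime$r2_branch == "insp") "23"
  else "4"
}

#' @export
print.flow_regime <- function(x, ...) {
  cat(sprintf("flow regime: R1 %s branch, R2 %s branch (region %s)\n",
              x$r1_branch, x$r2_branch, region_label(x)))
  invisible(x)
}

#' Active resistances under a flow regime
#'
#' @param regime a \code{\link{flow_regime}}.
#' @param p an \code{\link{airflow_params}} object.
#' @return Named numeric vector \code{c(R1 = , R2 = )} in cmH2O/(L/s).
#' @examples
#' p <- airflow_params()
#' regime_resistances(flow_regime("insp", "insp"), p)  # R1 = 1, R2 = 100
#' @export
regime_resistances <- function(regime, p) {
  c(R1 = if (regime$r1_branch == "insp") p$R1_insp else p$R1_exp,
    R2 = if (regime$r2_branch == "exp") p$R2_exp else p$R2_insp)
}

# combined resistance Rbar = R1 R2 + R2 RT + RT R1
.rbar <- function(R1, R2, RT) R1 * R2 + R2 * RT + RT * R1

#' Branch flows and junction pressure
#'
#' Computes the tracheal flow \code{qT}, the mesobronchial flow into the
#' caudal airsacs \code{q1}, the ventrobronchial flow out of the cranial
#' airsacs \code{q2}, the parabronchial flow \code{qP}, and the junction
#' pressure \code{PJ}, for states expressed as pressure deviations from
#' atmosphere, \code{x_i = P_i - P_atm}.  With \code{Rbar = R1*R2 + R2*R_T +
#' R_T*R1}:
#' \deqn{q_T = (-R_2 x_1 - R_1 x_2)/\bar R, \quad
#'       q_1 = (-R_2 x_1 - R_T(x_1 - x_2))/\bar R,}
#' \deqn{q_2 = (R_1 x_2 - R_T(x_1 - x_2))/\bar R, \quad
#'       q_P = (x_1 - x_2)/R_P.}
#' Junction conservation \code{qT + q2 = q1} holds identically.  All flows are
#' single-side, in L/s.
#'
#' @param x1,x2 caudal / cranial airsac pressure deviations from atmospheric
#'   (cmH2O); vectorised.
#' @param regime a \code{\link{flow_regime}} selecting the active resistances.
#' @param p an \code{\link{airflow_params}} object.
#' @return A data frame with columns \code{qT, q1, q2, qP} (L/s) and
#'   \code{PJ} (cmH2O).
#' @export
compute_flows <- function(x1, x2, regime, p) {
  r <- regime_resistances(regime, p)
  flows_from_resistances(x1, x2, r[["R1"]], r[["R2"]], p)
}

# internal work-horse, also used with explicit branch resistances
flows_from_resistances <- function(x1, x2, R1, R2, p) {
  RT <- p$R_T
  rb <- .rbar(R1, R2, RT)
  d <- x1 - x2
  data.frame(
    qT = (-R2 * x1 - R1 * x2) / rb,
    q1 = (-R2 * x1 - RT * d) / rb,
    q2 = (R1 * x2 - RT * d) / rb,
    qP = d / p$R_P,
    PJ = (R2 * RT * (x1 + p$P_atm) + RT * R1 * (x2 + p$P_atm) +
            R1 * R2 * p$P_atm) / rb
  )
}

#' Frozen-regime system matrix
#'
#' Within a fixed regime the pressure deviations obey the linear system
#' \code{dX/dt = A X + (dP_ext/dt) [1, 1]'} with
#' \deqn{A = \begin{pmatrix}
#'  -(\beta + R_P R_2)/(C_1 \bar R R_P) & \beta/(C_1 \bar R R_P) \\
#'  \beta/(C_2 \bar R R_P) & -(\beta + R_P R_1)/(C_2 \bar R R_P)
#' \end{pmatrix}}
#' where \eqn{\beta = R_T R_P + \bar R}.  Compliances enter in L/cmH2O so the
#' entries have units 1/s.
#'
#' @inheritParams compute_flows
#' @return A 2x2 numeric matrix.
#' @export
system_matrix <- function(regime, p) {
  pc <- .consistent(p)
  r <- regime_resistances(regime, p)
  R1 <- r[["R1"]]; R2 <- r[["R2"]]; RT <- pc$R_T; RP <- pc$R_P
  rb <- .rbar(R1, R2, RT)
  beta <- RT * RP + rb
  matrix(c(-(beta + RP * R2) / (pc$C1 * rb * RP),
           beta / (pc$C2 * rb * RP),
           beta / (pc$C1 * rb * RP),
           -(beta + RP * R1) / (pc$C2 * rb * RP)),
         nrow = 2)
}

#' Time derivative of the transformed pressures
#'
#' Evaluates \code{dX/dt = A X + (dP_ext/dt) [1, 1]'} for the frozen-regime
#' linear system, where \code{X = (x1, x2)} are the airsac pressure deviations
#' from atmosphere.
#'
#' @param t time (s).
#' @param x numeric vector \code{c(x1, x2)} (cmH2O).
#' @inheritParams compute_flows
#' @return Numeric vector \code{c(dx1dt, dx2dt)} (cmH2O/s).
#' @export
state_derivative <- function(t, x, regime, p) {
  A <- system_matrix(regime, p)
  drop(A %*% x) + external_pressure_rate(t, p)
}

#' Airsac volumes
#'
#' The airsacs are elastic: \code{V_i = C_i (P_i - P_ext(t)) + V_i_res}, with
#' \code{P_i = x_i + P_atm}.  Volumes are single-side, in mL.
#'
#' @param x1,x2 pressure deviations from atmospheric (cmH2O); vectorised.
#' @param t time (s), used to evaluate the external pressure.
#' @param p an \code{\link{airflow_params}} object.
#' @return A data frame with columns \code{V1} and \code{V2} (mL).
#' @export
airsac_volumes <- function(x1, x2, t, p) {
  pe <- external_pressure(t, p)
  V1 <- p$C1 * (x1 + p$P_atm - pe) + p$V1_res
  V2 <- p$C2 * (x2 + p$P_atm - pe) + p$V2_res
  if (any(V1 <= 0) || any(V2 <= 0))
    warning("non-positive airsac volume: the linear elastic airsac model ",
            "is outside its physical range for these parameters")
  data.frame(V1 = V1, V2 = V2)
}

#' Classify the phase-plane region of a state
#'
#' Determines which flow-sign region of the phase plane a state lies in,
#' evaluating each branch flow under the resistances that govern the
#' corresponding boundary: the \code{q1 = 0} boundary (region 1 vs 2/3) under
#' \code{R2 = R2_insp}; the \code{q2 = 0} boundary (regions 2/3 vs 4) under
#' \code{R1 = R1_exp}; and the inspiration/expiration boundary \code{qT = 0}
#' under \code{R1 = R1_exp, R2 = R2_insp} (it lies in the lower-right
#' quadrant, inside regions 2/3).  A flow exactly at zero is classified with
#' its preferred direction (\code{q1 >= 0} counts as inspiratory branch,
#' \code{q2 <= 0} as inspiratory branch), so the equilibrium maps to
#' region 1.
#'
#' @param x1,x2 pressure deviations from atmospheric (cmH2O); scalars.
#' @param p an \code{\link{airflow_params}} object.
#' @return A list with \code{region} (\code{"1"}, \code{"23"} or \code{"4"}),
#'   \code{regime} (the corresponding \code{\link{flow_regime}}), and
#'   \code{signs}, the signs of \code{(qT, q1, q2)} evaluated under the
#'   boundary-governing resistances.
#' @export
classify_region <- function(x1, x2, p) {
  RT <- p$R_T
  d <- x1 - x2
  q1_num <- -p$R2_insp * x1 - RT * d          # q1 sign at the region-1 boundary
  q2_num <- p$R1_exp * x2 - RT * d            # q2 sign at the region-4 boundary
  qT_num <- -p$R2_insp * x1 - p$R1_exp * x2   # insp/exp boundary (regions 2/3)
  if (q1_num >= 0) {
    region <- "1"
    qT_sign <- 1  # region 1 lies inside the inspiratory half-plane
  } else if (q2_num > 0) {
    region <- "4"
    qT_sign <- -1
  } else {
    region <- "23"
    qT_sign <- sign(qT_num)
    if (qT_sign == 0) qT_sign <- 1
  }
  list(region = region,
       regime = regime_from_region(region),
       signs = c(qT = qT_sign,
                 q1 = if (q1_num >= 0) 1 else -1,
                 q2 = if (q2_num > 0) 1 else -1))
}
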