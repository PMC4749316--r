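#' Scaled frozen-regime system matrix
#'
#' Scaling time by \code{C1 * Rbar * R_P} turns the frozen-regime system
#' matrix into the dimensionless-time form
#' \deqn{\hat A = \begin{pmatrix} -(R_2 R_P + \beta) & \beta \\
#'   \gamma\beta & -\gamma(R_1 R_P + \beta) \end{pmatrix}, \qquad
#'   \beta = R_T R_P + \bar R,}
#' which has the same phase-plane geometry (eigenvectors, trajectories) as the
#' unscaled matrix and eigenvalues equal to the unscaled ones multiplied by
#' \code{C1 * Rbar * R_P} (compliance in L/cmH2O).
#'
#' @param regime a \code{\link{flow_regime}}.
#' @param p an \code{\link{airflow_params}} object.
#' @return A list with \code{A_hat} (2x2 matrix), \code{beta}, and
#'   \code{scale}, the time-scaling factor \code{C1 * Rbar * R_P} (s).
#' @export
scaled_system_matrix <- function(regime, p) {
  r <- regime_resistances(regime, p)
  R1 <- r[["R1"]]; R2 <- r[["R2"]]; RT <- p$R_T; RP <- p$R_P
  rb <- .rbar(R1, R2, RT)
  beta <- RT * RP + rb
  g <- p$gamma
  A_hat <- matrix(c(-(R2 * RP + beta), g * beta,
                    beta, -g * (R1 * RP + beta)), nrow = 2)
  list(A_hat = A_hat, beta = beta, scale = (p$C1 / 1000) * rb * RP)
}

#' Eigen-analysis of the frozen-regime system
#'
#' Closed-form eigenvalues and eigenvectors of the scaled system matrix
#' \eqn{\hat A}.  With \eqn{Tr(\hat A) = -(\gamma R_1 + R_2) R_P -
#' (\gamma + 1)\beta} and \eqn{Det(\hat A) = \gamma (R_1 R_2 R_P^2 +
#' \beta (R_1 + R_2) R_P)}, the eigenvalues are
#' \deqn{\lambda_{1,2} = \frac{Tr \mp \sqrt{Tr^2 - 4 Det}}{2},}
#' both real and negative for any positive parameters (the discriminant is
#' provably positive), with \eqn{\lambda_1 < \lambda_2 < 0}.  The
#' eigenvectors, normalised to first component 1, are
#' \eqn{V_i = [1, (\lambda_i + R_P R_2 + \beta)/\beta]'}; \eqn{V_1} is the
#' fast direction and \eqn{V_2} the slow direction along which trajectories
#' of the unforced system approach the origin.
#'
#' @inheritParams scaled_system_matrix
#' @return An object of class \code{"eigen_analysis"}: a list with
#'   \code{A_hat}, \code{beta}, \code{trace}, \code{determinant},
#'   \code{discriminant}, \code{lambda1}, \code{lambda2} (scaled, fast/slow),
#'   \code{V1_fast}, \code{V2_slow} (length-2 vectors, first component 1),
#'   and \code{scale} for converting eigenvalues back to 1/s.
#' @examples
#' p <- airflow_params(gamma = 1, R1_insp = 3, R2_insp = 3,
#'                     R1_exp = 3, R2_exp = 3)
#' ea <- eigen_analysis(flow_regime("insp", "insp"), p)
#' ea$lambda1  # -195.5
#' ea$lambda2  # -7.5
#' @export
eigen_analysis <- function(regime, p) {
  s <- scaled_system_matrix(regime, p)
  r <- regime_resistances(regime, p)
  R1 <- r[["R1"]]; R2 <- r[["R2"]]; RP <- p$R_P
  g <- p$gamma; beta <- s$beta
  tr <- -(g * R1 + R2) * RP - (g + 1) * beta
  det <- g * (R1 * R2 * RP^2 + beta * (R1 + R2) * RP)
  disc <- tr^2 - 4 * det
  stopifnot(disc > 0)  # provable for positive parameters
  l1 <- (tr - sqrt(disc)) / 2
  l2 <- (tr + sqrt(disc)) / 2
  v <- function(l) c(1, (l + RP * R2 + beta) / beta)
  # label fast/slow by eigenvalue magnitude; coincides with the formula order
  stopifnot(abs(l1) >= abs(l2))
  structure(list(A_hat = s$A_hat, beta = beta, trace = tr,
                 determinant = det, discriminant = disc,
                 lambda1 = l1, lambda2 = l2,
                 V1_fast = v(l1), V2_slow = v(l2),
                 scale = s$scale, regime = regime),
            class = "eigen_analysis")
}

#' @export
print.eigen_analysis <- function(x, ...) {
  cat(sprintf("Frozen-regime eigen-analysis (region %s)\n",
              region_label(x$regime)))
  cat(sprintf("  trace = %.6g, det = %.6g, discriminant = %.6g\n",
              x$trace, x$determinant, x$discriminant))
  cat(sprintf("  lambda1 (fast) = %.6g, lambda2 (slow) = %.6g (scaled time)\n",
              x$lambda1, x$lambda2))
  cat(sprintf("  = %.6g, %.6g 1/s (unscaled)\n",
              x$lambda1 / x$scale, x$lambda2 / x$scale))
  cat(sprintf("  V_fast = [1, %.6g], V_slow = [1, %.6g]\n",
              x$V1_fast[2], x$V2_slow[2]))
  invisible(x)
}

#' Eigenpairs in the even-compliance special case
#'
#' For \code{gamma = 1} (equal airsac compliances) the eigenvalues of the
#' scaled matrix reduce to
#' \deqn{\lambda_{1,2} = -\tfrac12\left[(R_1 + R_2) R_P + 2\beta \pm
#'   \sqrt{(R_2 - R_1)^2 R_P^2 + 4\beta^2}\right]}
#' with eigenvectors
#' \eqn{V_{1,2} = [1, (\tfrac12 (R_2 - R_1) R_P \mp \tfrac12
#' \sqrt{(R_2 - R_1)^2 R_P^2 + 4\beta^2})/\beta]'}.  When additionally
#' \code{R1 = R2} these become \eqn{\lambda_1 = -\tfrac12(R_1 + R_2) R_P -
#' 2\beta}, \eqn{\lambda_2 = -\tfrac12 (R_1 + R_2) R_P} with eigenvectors
#' \code{[1, -1]} and \code{[1, 1]}.
#'
#' @inheritParams scaled_system_matrix
#' @return A list with \code{lambda1}, \code{lambda2}, \code{V1_fast},
#'   \code{V2_slow}, matching \code{\link{eigen_analysis}}.
#' @export
special_case_eigen <- function(regime, p) {
  if (abs(p$gamma - 1) > 1e-12)
    stop("special_case_eigen requires gamma = 1 (got gamma = ", p$gamma, ")",
         call. = FALSE)
  s <- scaled_system_matrix(regime, p)
  r <- regime_resistances(regime, p)
  R1 <- r[["R1"]]; R2 <- r[["R2"]]; RP <- p$R_P; beta <- s$beta
  root <- sqrt((R2 - R1)^2 * RP^2 + 4 * beta^2)
  l1 <- -0.5 * ((R1 + R2) * RP + 2 * beta + root)
  l2 <- -0.5 * ((R1 + R2) * RP + 2 * beta - root)
  list(lambda1 = l1, lambda2 = l2,
       V1_fast = c(1, (0.5 * (R2 - R1) * RP - 0.5 * root) / beta),
       V2_slow = c(1, (0.5 * (R2 - R1) * RP + 0.5 * root) / beta))
}

#' Certificate for unidirectional parabronchial flow
#'
#' Phase-plane analysis shows that the parabronchial flow is unidirectional
#' (\code{qP > 0}) when \code{gamma * R1 <= R2} during inspiration and
#' \code{gamma * R1 >= R2} during expiration, where \code{gamma = C1/C2}.  In
#' the borderline case where both hold with equality the slow eigenvector
#' lies along \code{x2 = x1} in both regimes, the forced trajectory oscillates
#' on that line, and \code{qP} is identically zero.  A valve is classified as
#' effective when its inequality is strict.
#'
#' @param p an \code{\link{airflow_params}} object.
#' @return An object of class \code{"valving_certificate"}: a list with
#'   \code{insp_condition}, \code{exp_condition} (logical, with the compared
#'   quantities as attributes), \code{verdict} (\code{"unidirectional"},
#'   \code{"borderline"}, or \code{"violated"}), and \code{effective_valves}
#'   (\code{"both"}, \code{"inspiratory"}, \code{"expiratory"}, or
#'   \code{"none"}).
#' @examples
#' unidirectional_flow_condition(airflow_params())$verdict  # "unidirectional"
#' @export
unidirectional_flow_condition <- function(p) {
  g <- p$gamma
  insp_lhs <- g * p$R1_insp; insp_rhs <- p$R2_insp
  exp_lhs <- g * p$R1_exp;  exp_rhs <- p$R2_exp
  tol <- 1e-12 * max(insp_rhs, exp_lhs)
  insp_ok <- insp_lhs <= insp_rhs + tol
  exp_ok <- exp_lhs >= exp_rhs - tol
  insp_strict <- insp_lhs < insp_rhs - tol
  exp_strict <- exp_lhs > exp_rhs + tol
  verdict <- if (insp_ok && exp_ok && (insp_strict || exp_strict))
    "unidirectional"
  else if (insp_ok && exp_ok) "borderline"
  else "violated"
  effective <- if (insp_strict && exp_strict) "both"
  else if (insp_strict) "inspiratory"
  else if (exp_strict) "expiratory"
  else "none"
  structure(list(
    insp_condition = structure(insp_ok, gammaR1 = insp_lhs, R2 = insp_rhs),
    exp_condition = structure(exp_ok, gammaR1 = exp_lhs, R2 = exp_rhs),
    verdict = verdict,
    effective_valves = effective
  ), class = "valving_certificate")
}

#' @export
print.valving_certificate <- function(x, ...) {
  cat("Unidirectional-flow certificate\n")
  cat(sprintf("  inspiration: gamma*R1 = %.4g %s R2 = %.4g\n",
              attr(x$insp_condition, "gammaR1"),
              if (x$insp_condition) "<=" else ">",
              attr(x$insp_condition, "R2")))
  cat(sprintf("  expiration:  gamma*R1 = %.4g %s R2 = %.4g\n",
              attr(x$exp_condition, "gammaR1"),
              if (x$exp_condition) ">=" else "<",
              attr(x$exp_condition, "R2")))
  cat(sprintf("  verdict: %s (effective valves: %s)\n",
              x$verdict, x$effective_valves))
  invisible(x)
}
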