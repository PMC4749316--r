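# trapezoidal rule on an (irregular) grid
.trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1]) / 2)

#' Trapezoidal volume of a flow over a breath or phase interval
#'
#' Integrates one of the sampled flows of a steady-state breath by the
#' trapezoidal method.  Phase intervals are cut at the event-located zero
#' crossings of \code{qT}, which are exact sample points of the series, so
#' the integral boundaries carry no grid-rounding error.
#'
#' @param sim a \code{\link{simulate_airflow}} result.
#' @param flow one of \code{"qT"}, \code{"q1"}, \code{"q2"}, \code{"qP"}.
#' @param interval \code{"breath"} (the full cycle), \code{"insp"}
#'   (\code{qT > 0}) or \code{"exp"} (\code{qT < 0}).
#' @return Volume in litres (single side).
#' @export
integrate_flow <- function(sim, flow = c("qT", "q1", "q2", "qP"),
                           interval = c("breath", "insp", "exp")) {
  flow <- match.arg(flow)
  interval <- match.arg(interval)
  s <- sim$series
  if (interval == "breath")
    return(.trapz(s$t, s[[flow]]))
  ph <- detect_phase_boundaries(sim)
  ph <- ph[ph$phase == toupper(interval), , drop = FALSE]
  if (nrow(ph) == 0L)
    stop("the breath has no ", interval, " interval", call. = FALSE)
  tot <- 0
  for (i in seq_len(nrow(ph))) {
    idx <- s$t >= ph$start[i] - 1e-12 & s$t <= ph$end[i] + 1e-12
    tot <- tot + .trapz(s$t[idx], s[[flow]][idx])
  }
  tot
}

#' Breath-cycle summary metrics
#'
#' Computes the standard summary quantities of a steady-state breath:
#' \describe{
#'   \item{tidal_volume}{inhaled volume per breath,
#'     \eqn{\int_{INSP} q_T\,dt} (mL).}
#'   \item{parabronchial_volume}{volume through the gas-exchanging
#'     parabronchi per breath, \eqn{\int_{breath} q_P\,dt} (mL).}
#'   \item{efficiency}{fraction of the tidal volume passing through the
#'     parabronchi, \eqn{\int_{breath} q_P\,dt / \int_{INSP} q_T\,dt}.}
#'   \item{insp_valving_efficacy}{fraction of inhaled air reaching the caudal
#'     airsacs, \eqn{\int_{INSP} q_1\,dt / \int_{INSP} q_T\,dt}.}
#'   \item{exp_valving_efficacy}{fraction of exhaled air originating from the
#'     cranial airsacs, \eqn{\int_{EXP} q_2\,dt / \int_{EXP} (-q_T)\,dt}.}
#'   \item{exp_valving_efficacy_alt}{the alternative literature definition:
#'     parabronchial outflow as a share of the total expiratory outflow from
#'     the caudal airsacs,
#'     \eqn{\int_{EXP} q_P\,dt / \int_{EXP} (q_P + \max(-q_1, 0))\,dt}.  The
#'     back-leak term \eqn{-q_1} is clamped at zero sample-wise so the share
#'     stays in [0, 1] even when \eqn{q_1} momentarily exceeds zero near a
#'     phase boundary.}
#'   \item{ie_flow_ratio}{inspiratory over expiratory parabronchial volume,
#'     \eqn{\int_{INSP} q_P\,dt / \int_{EXP} q_P\,dt}.}
#'   \item{T_i, T_e, ie_time_ratio}{durations of inspiration (\eqn{q_T > 0})
#'     and expiration (\eqn{q_T < 0}) and their ratio.}
#'   \item{ventilation_caudal, ventilation_cranial}{airsac ventilation
#'     volumes \eqn{\max V_i - \min V_i} (mL); independent of \code{P_c} and
#'     \code{V_i_res}.}
#'   \item{caudal_ventilation_fraction}{caudal share of the total airsac
#'     ventilation.}
#'   \item{peak_V1, peak_V2}{end-inspiratory airsac volumes (mL).}
#' }
#' Flows in the reduced model describe a single side of the symmetric system;
#' with \code{whole_animal = TRUE} (the default) volumes are doubled.
#' Dimensionless ratios are unaffected by the doubling.
#'
#' @param sim a \code{\link{simulate_airflow}} result.
#' @param whole_animal logical; double single-side volumes to whole-animal
#'   values.
#' @return An object of class \code{"breath_metrics"} (a named list).
#' @examples
#' \donttest{
#' sim <- simulate_airflow(airflow_params(), dt = 1e-3)
#' breath_metrics(sim)
#' }
#' @export
breath_metrics <- function(sim, whole_animal = TRUE) {
  mult <- if (whole_animal) 2 else 1
  s <- sim$series
  ph <- detect_phase_boundaries(sim)
  insp_qT <- integrate_flow(sim, "qT", "insp")
  exp_qT <- integrate_flow(sim, "qT", "exp")
  insp_q1 <- integrate_flow(sim, "q1", "insp")
  exp_q2 <- integrate_flow(sim, "q2", "exp")
  insp_qP <- integrate_flow(sim, "qP", "insp")
  exp_qP <- integrate_flow(sim, "qP", "exp")
  breath_qP <- integrate_flow(sim, "qP", "breath")
  if (insp_qT <= 0)
    stop("zero tidal volume: breath metrics are undefined", call. = FALSE)

  # alternative expiratory efficacy: qP as a share of total caudal outflow
  exp_rows <- which(s$phase == "EXP" | abs(s$t - ph$start[ph$phase == "EXP"][1]) < 1e-12)
  te <- s$t[exp_rows]
  alt_den <- .trapz(te, s$qP[exp_rows] + pmax(-s$q1[exp_rows], 0))
  alt <- if (alt_den > 0) .trapz(te, s$qP[exp_rows]) / alt_den else NA_real_

  T_i <- sum(ph$end[ph$phase == "INSP"] - ph$start[ph$phase == "INSP"])
  T_e <- sum(ph$end[ph$phase == "EXP"] - ph$start[ph$phase == "EXP"])

  dV1 <- (max(s$V1) - min(s$V1)) * mult
  dV2 <- (max(s$V2) - min(s$V2)) * mult

  structure(list(
    tidal_volume = insp_qT * 1000 * mult,
    parabronchial_volume = breath_qP * 1000 * mult,
    efficiency = breath_qP / insp_qT,
    insp_valving_efficacy = insp_q1 / insp_qT,
    exp_valving_efficacy = exp_q2 / (-exp_qT),
    exp_valving_efficacy_alt = alt,
    ie_flow_ratio = if (exp_qP != 0) insp_qP / exp_qP else NA_real_,
    T_i = T_i, T_e = T_e,
    ie_time_ratio = if (T_e > 0) T_i / T_e else NA_real_,
    ventilation_caudal = dV1,
    ventilation_cranial = dV2,
    caudal_ventilation_fraction = dV1 / (dV1 + dV2),
    peak_V1 = max(s$V1) * mult,
    peak_V2 = max(s$V2) * mult,
    whole_animal = whole_animal
  ), class = "breath_metrics")
}

#' @export
print.breath_metrics <- function(x, ...) {
  side <- if (x$whole_animal) "whole animal" else "single side"
  cat("Breath metrics (", side, ")\n", sep = "")
  cat(sprintf("  tidal volume            %7.1f mL\n", x$tidal_volume))
  cat(sprintf("  parabronchial volume    %7.1f mL/breath\n",
              x$parabronchial_volume))
  cat(sprintf("  efficiency              %7.1f %%\n", 100 * x$efficiency))
  cat(sprintf("  insp valving efficacy   %7.1f %%\n",
              100 * x$insp_valving_efficacy))
  cat(sprintf("  exp valving efficacy    %7.1f %% (alt definition %.1f %%)\n",
              100 * x$exp_valving_efficacy, 100 * x$exp_valving_efficacy_alt))
  cat(sprintf("  I:E parabronchial flow  %7.3f\n", x$ie_flow_ratio))
  cat(sprintf("  T_i = %.3f s, T_e = %.3f s, I:E time ratio %.3f\n",
              x$T_i, x$T_e, x$ie_time_ratio))
  cat(sprintf("  ventilation: caudal %.1f mL, cranial %.1f mL (caudal fraction %.3f)\n",
              x$ventilation_caudal, x$ventilation_cranial,
              x$caudal_ventilation_fraction))
  invisible(x)
}
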