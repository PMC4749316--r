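#' @export
print.airflow_sim <- function(x, ...) {
  cat("Avian airflow simulation (switched two-compartment model)\n")
  cat(sprintf("  %s after %d breaths (net tracheal volume %.2e L)\n",
              if (x$converged) "converged" else "NOT converged",
              x$breaths, x$net_tracheal_volume))
  cat(sprintf("  final breath: %.4f s, %d samples (dt = %g s), min qP = %.4g L/s\n",
              x$duration, nrow(x$series), x$dt, min(x$series$qP)))
  cat("  use summary() for breath metrics, plot() for the waveforms\n")
  invisible(x)
}

#' @export
summary.airflow_sim <- function(object, whole_animal = TRUE, ...) {
  structure(list(sim = object,
                 metrics = breath_metrics(object, whole_animal),
                 certificate = unidirectional_flow_condition(object$params)),
            class = "summary.airflow_sim")
}

#' @export
print.summary.airflow_sim <- function(x, ...) {
  print(x$sim)
  cat("\n")
  print(x$certificate)
  cat("\n")
  print(x$metrics)
  invisible(x)
}

#' @export
coef.airflow_sim <- function(object, ...) {
  p <- object$params
  unlist(p[c("P_atm", "R_trachea", "R_EPPB", "R_T", "R_P",
             "R1_insp", "R2_insp", "R1_exp", "R2_exp",
             "gamma", "C_tot", "C1", "C2", "V1_res", "V2_res",
             "P_c", "P_amp", "T")])
}

#' Plot a simulated breath
#'
#' Three stacked panels over one steady-state breath: airsac pressure
#' deviations from atmosphere, branch flows, and airsac volumes, with the
#' inspiration/expiration boundary marked.
#'
#' @param x an \code{\link{simulate_airflow}} result.
#' @param ... ignored.
#' @export
plot.airflow_sim <- function(x, ...) {
  s <- x$series
  tq <- x$events$t[x$events$kind == "qT_zero"]
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  mark <- function() graphics::abline(v = tq, lty = 3, col = "grey40")
  graphics::matplot(s$t, cbind(s$x1, s$x2), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "time (s)", ylab = "pressure - atm (cmH2O)")
  graphics::legend("topright", c("x1 (caudal)", "x2 (cranial)"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  mark()
  graphics::matplot(s$t, cbind(s$qT, s$q1, s$q2, s$qP), type = "l", lty = 1,
                    col = c("black", "firebrick", "steelblue", "darkgreen"),
                    xlab = "time (s)", ylab = "flow (L/s, single side)")
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", c("qT", "q1", "q2", "qP"),
                   col = c("black", "firebrick", "steelblue", "darkgreen"),
                   lty = 1, bty = "n")
  mark()
  graphics::matplot(s$t, cbind(s$V1, s$V2), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "time (s)", ylab = "volume (mL, single side)")
  graphics::legend("topright", c("V1 (caudal)", "V2 (cranial)"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  mark()
  invisible(x)
}
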