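#' External (coelomic) pressure driving the airsacs
#'
#' The respiratory muscles are modelled as a sinusoidal pressure in the
#' thoracic-abdominal cavity surrounding both sets of airsacs,
#' \deqn{P_{ext}(t) = P_c - \frac{P_{amp}}{2}\cos(2\pi t/T),}
#' oscillating with peak-to-peak amplitude \code{P_amp} about the baseline
#' coelomic pressure \code{P_c} with period \code{T}.
#'
#' @param t time (s); vectorised.
#' @param p an \code{\link{airflow_params}} object.
#' @return Pressure (cmH2O) for \code{external_pressure}; its time derivative
#'   (cmH2O/s) for \code{external_pressure_rate}.
#' @examples
#' p <- airflow_params()
#' external_pressure(0, p)        # P_c - P_amp/2
#' external_pressure(p$T / 2, p)  # P_c + P_amp/2
#' @export
external_pressure <- function(t, p) {
  p$P_c - (p$P_amp / 2) * cos(2 * pi * t / p$T)
}

#' @rdname external_pressure
#' @export
external_pressure_rate <- function(t, p) {
  p$P_amp * (pi / p$T) * sin(2 * pi * t / p$T)
}
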