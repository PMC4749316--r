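# Event-driven simulation of the switched linear system.
#
# Within a regime the model is a 2-D linear ODE with sinusoidal forcing,
#   dX/dt = A X + alpha sin(omega t) [1,1]',
# so the trajectory is known in closed form from the eigendecomposition of A
# and the complex particular solution z = (i omega I - A)^{-1} alpha [1,1]'.
# Legs are propagated exactly and resistance-switching events (zero crossings
# of q1, q2) and phase events (zero crossings of qT) are located by scanning
# the closed-form flow and refining the bracket with uniroot.

.regime_dyn <- function(regime, p) {
  A <- system_matrix(regime, p)
  e <- eigen(A)
  lambda <- Re(e$values)
  V <- Re(e$vectors)
  omega <- 2 * pi / p$T
  alpha <- p$P_amp * pi / p$T
  z <- if (p$P_amp > 0) {
    solve(diag(2) * (0 + 1i) * omega - A, c(alpha, alpha))
  } else c(0 + 0i, 0 + 0i)
  r <- regime_resistances(regime, p)
  list(A = A, lambda = lambda, V = V, Vinv = solve(V),
       omega = omega, z = z, forced = p$P_amp > 0,
       R1 = r[["R1"]], R2 = r[["R2"]], RT = p$R_T,
       rb = .rbar(r[["R1"]], r[["R2"]], p$R_T), regime = regime)
}

.dyn_cache <- function(p) {
  list("1" = .regime_dyn(regime_from_region("1"), p),
       "23" = .regime_dyn(regime_from_region("23"), p),
       "4" = .regime_dyn(regime_from_region("4"), p))
}

# particular solution, 2 x length(t)
.xp <- function(dyn, t) {
  if (!dyn$forced) return(matrix(0, 2, length(t)))
  e <- exp((0 + 1i) * dyn$omega * t)
  rbind(Im(dyn$z[1] * e), Im(dyn$z[2] * e))
}

# leg-local coefficients for the homogeneous part
.leg_coef <- function(dyn, t0, X0) {
  drop(dyn$Vinv %*% (X0 - .xp(dyn, t0)[, 1]))
}

# state at times t for a leg started at (t0, X0); returns 2 x length(t)
.leg_state <- function(dyn, c0, t0, t) {
  E <- exp(outer(dyn$lambda, t - t0))
  dyn$V %*% (c0 * E) + .xp(dyn, t)
}

# numerators of the watched flows (same sign as the flow; Rbar > 0)
.flow_num <- function(dyn, X, flow) {
  d <- X[1, ] - X[2, ]
  switch(flow,
         qT = -dyn$R2 * X[1, ] - dyn$R1 * X[2, ],
         q1 = -dyn$R2 * X[1, ] - dyn$RT * d,
         q2 = dyn$R1 * X[2, ] - dyn$RT * d)
}

# exact integral of qT over [t0, t1] for a leg (litres)
.leg_qT_integral <- function(dyn, c0, t0, t1) {
  lam <- dyn$lambda
  Ih <- drop(dyn$V %*% (c0 * (exp(lam * (t1 - t0)) - 1) / lam))
  Ip <- if (dyn$forced) {
    e <- (exp((0 + 1i) * dyn$omega * t1) - exp((0 + 1i) * dyn$omega * t0)) /
      ((0 + 1i) * dyn$omega)
    c(Im(dyn$z[1] * e), Im(dyn$z[2] * e))
  } else c(0, 0)
  Ix <- Ih + Ip
  (-dyn$R2 * Ix[1] - dyn$R1 * Ix[2]) / dyn$rb
}

# locate the first zero crossing of any watched flow after t0.
# watch: named numeric vector of expected interior signs, e.g. c(q1 = 1).
# Returns list(t, flow, X) or signals an error if nothing crosses within
# `horizon`.  Sign violations count only above a relative floor so that
# rounding noise near a just-located event cannot masquerade as a crossing;
# when no significant correct-sign value precedes the first violation the
# crossing coincides with the leg start and is reported as a zero-length
# event at t0 (these arise legitimately in borderline gamma*R1 = R2
# configurations, where q1 and q2 cross zero at the same instant).
.next_crossing <- function(dyn, c0, t0, watch, horizon, h = 1e-3) {
  flows <- names(watch)
  ts <- unique(c(t0, t0 + 10^seq(-9, log10(h) - 0.25, by = 0.35),
                 seq(t0 + h, t0 + horizon, by = h), t0 + horizon))
  X <- .leg_state(dyn, c0, t0, ts)
  best <- NULL
  for (fl in flows) {
    g <- .flow_num(dyn, X, fl) * watch[[fl]]
    floor_g <- 1e-9 * max(abs(g))
    if (floor_g == 0) next
    viol <- which(g < -floor_g)
    if (!length(viol)) next
    j <- viol[1]
    ok <- which(g[seq_len(j - 1L)] > floor_g)
    if (!length(ok)) {
      cand <- list(t = t0, flow = fl, X = X[, 1])
    } else {
      k <- max(ok)
      f <- function(tt) .flow_num(dyn, .leg_state(dyn, c0, t0, tt), fl)
      root <- stats::uniroot(f, lower = ts[k], upper = ts[j],
                             f.lower = g[k] * watch[[fl]],
                             f.upper = g[j] * watch[[fl]],
                             tol = 1e-13)$root
      cand <- list(t = root, flow = fl,
                   X = .leg_state(dyn, c0, t0, root)[, 1])
    }
    if (is.null(best) || cand$t < best$t - 1e-12 ||
        (abs(cand$t - best$t) <= 1e-12 && fl == "qT"))
      best <- cand
  }
  if (!is.null(best)) return(best)
  stop("no flow-switching event found within ", horizon, " s (about two ",
       "breathing periods): the dynamics are degenerate for this parameter ",
       "set (e.g. P_amp = 0 gives an unforced, decaying system in which no ",
       "breath completes)", call. = FALSE)
}

# sample a completed leg on a uniform dt grid, endpoints included
.sample_leg <- function(dyn, c0, t0, t1, dt, p) {
  ts <- seq(t0, t1, by = dt)
  if (ts[length(ts)] < t1 - 1e-12) ts <- c(ts, t1) else ts[length(ts)] <- t1
  X <- .leg_state(dyn, c0, t0, ts)
  fl <- flows_from_resistances(X[1, ], X[2, ], dyn$R1, dyn$R2, p)
  vol <- suppressWarnings(airsac_volumes(X[1, ], X[2, ], ts, p))
  data.frame(t = ts, x1 = X[1, ], x2 = X[2, ], fl, vol,
             region = region_label(dyn$regime))
}

# core event loop.  Advances the hybrid system from (t0, X0, region) until
# `n_switches` resistance switches have occurred, or (if stop_at_qT_up) until
# the next upward zero crossing of qT.  Optionally samples every leg.
.run_legs <- function(p, dyn, t0, X0, region, qT_sign,
                      n_switches = Inf, stop_at_qT_up = FALSE,
                      dt = NULL, max_legs = 200) {
  horizon <- 2 * p$T
  events <- list()
  samples <- list()
  net_qT <- 0
  n_sw <- 0L
  zero_run <- 0L
  last_switch_flow <- ""
  for (i in seq_len(max_legs)) {
    dyn_r <- dyn[[region]]
    watch <- switch(region,
                    "1" = c(q1 = 1),
                    "4" = c(q2 = 1),
                    "23" = c(q1 = -1, q2 = -1, qT = qT_sign))
    c0 <- .leg_coef(dyn_r, t0, X0)
    ev <- .next_crossing(dyn_r, c0, t0, watch, horizon)
    if (!is.null(dt) && ev$t > t0)
      samples[[length(samples) + 1L]] <- .sample_leg(dyn_r, c0, t0, ev$t, dt, p)
    net_qT <- net_qT + .leg_qT_integral(dyn_r, c0, t0, ev$t)
    if (ev$t - t0 < 1e-9) {
      zero_run <- zero_run + 1L
      if (zero_run > 6L)
        stop("repeated zero-length legs: sliding along a switching surface",
             call. = FALSE)
      if (ev$flow == last_switch_flow)
        stop("flow '", ev$flow, "' re-crossed zero immediately after its ",
             "switch: sliding along the switching surface (chatter) is not ",
             "supported", call. = FALSE)
    } else zero_run <- 0L
    if (ev$flow == "qT") {
      events[[length(events) + 1L]] <- data.frame(t = ev$t, kind = "qT_zero")
      qT_sign <- -qT_sign
      if (stop_at_qT_up && qT_sign > 0) {
        return(list(t = ev$t, X = ev$X, region = region, qT_sign = qT_sign,
                    events = do.call(rbind, events), n_switches = n_sw,
                    series = if (length(samples)) do.call(rbind, samples),
                    net_qT = net_qT))
      }
    } else {
      events[[length(events) + 1L]] <-
        data.frame(t = ev$t, kind = paste0(ev$flow, "_zero"))
      region <- switch(region,
                       "1" = "23",
                       "23" = if (ev$flow == "q2") "4" else "1",
                       "4" = "23")
      last_switch_flow <- ev$flow
      n_sw <- n_sw + 1L
      if (n_sw >= n_switches) {
        return(list(t = ev$t, X = ev$X, region = region, qT_sign = qT_sign,
                    events = do.call(rbind, events), n_switches = n_sw,
                    series = if (length(samples)) do.call(rbind, samples),
                    net_qT = net_qT))
      }
    }
    t0 <- ev$t
    X0 <- ev$X
  }
  stop("event loop exceeded ", max_legs, " legs without completing",
       call. = FALSE)
}

# merge per-leg samples: drop the duplicated leg-boundary rows
.merge_series <- function(series) {
  keep <- c(TRUE, diff(series$t) > 1e-13)
  series[keep, , drop = FALSE]
}

#' Simulate a single breath of the switched system
#'
#' Advances the model through one full breath cycle: four resistance-switch
#' events, following the sequence region 1 (\code{q1 = 0}) to regions 2/3
#' (\code{q2 = 0}) to region 4 (\code{q2 = 0}) to regions 2/3 (\code{q1 = 0})
#' and back to region 1 (or the same cycle entered at another region).  Zero
#' crossings of \code{qT} within regions 2/3 are located and recorded as
#' phase events without a resistance switch.
#'
#' @param state numeric vector \code{c(x1, x2)}, the starting pressure
#'   deviations from atmospheric (cmH2O).
#' @param t0 start time (s).
#' @param regime starting \code{\link{flow_regime}}; must be consistent with
#'   the flow signs of \code{state}.
#' @param p an \code{\link{airflow_params}} object.
#' @param dt output sampling step (s).
#' @return A list with \code{series} (sampled data frame: \code{t, x1, x2,
#'   qT, q1, q2, qP, PJ, V1, V2, region}), \code{events} (data frame
#'   \code{t, kind}), \code{end_state}, \code{end_regime}, \code{end_time},
#'   and \code{net_tracheal_volume}, the exact integral of \code{qT} over the
#'   breath (L, single side).
#' @export
simulate_breath <- function(state, t0 = 0, regime, p, dt = 1e-4) {
  p <- as_airflow_params(p)
  dyn <- .dyn_cache(p)
  region <- region_label(regime)
  qT_sign <- if (region == "1") 1
  else if (region == "4") -1
  else classify_region(state[1], state[2], p)$signs[["qT"]]
  out <- .run_legs(p, dyn, t0, state, region, qT_sign,
                   n_switches = 4, dt = dt)
  list(series = .merge_series(out$series), events = out$events,
       end_state = out$X, end_regime = regime_from_region(out$region),
       end_time = out$t, net_tracheal_volume = out$net_qT)
}

#' Simulate the avian airflow model to periodic steady state
#'
#' Integrates the switched two-compartment model from the rest state
#' \code{(x1, x2) = (0, 0)} at \code{t = 0}, breath by breath, until the net
#' tracheal volume over a breath (the integral of \code{qT}, flow in minus
#' flow out) falls below \code{steady_tol}, i.e. until the breath is
#' periodic.  The final converged breath is then re-simulated with dense
#' output, re-timed so that \code{t = 0} coincides with the start of
#' inspiration (the upward zero crossing of \code{qT}).
#'
#' @param p an \code{\link{airflow_params}} object (or a named list of
#'   arguments for it).
#' @param dt output sampling step for the final breath (s).
#' @param steady_tol convergence tolerance on the net tracheal volume per
#'   breath (L, single side).
#' @param max_breaths maximum number of breaths before giving up (with a
#'   warning and \code{converged = FALSE}).
#' @return An object of class \code{"airflow_sim"}: a list with
#'   \describe{
#'     \item{params}{the resolved parameters.}
#'     \item{series}{data frame sampling the final breath at \code{dt}:
#'       \code{t} (s, 0 at the start of inspiration), \code{x1, x2} (cmH2O),
#'       \code{qT, q1, q2, qP} (L/s, single side), \code{PJ} (cmH2O),
#'       \code{V1, V2} (mL, single side), \code{region}, \code{phase}
#'       (\code{"INSP"}/\code{"EXP"}).  Event times are included as sample
#'       points, so phase boundaries are exact rows.}
#'     \item{events}{data frame \code{t, kind} with kinds \code{q1_zero},
#'       \code{q2_zero}, \code{qT_zero}, \code{breath_end}.}
#'     \item{breaths}{number of breaths simulated before convergence.}
#'     \item{net_tracheal_volume}{net tracheal volume of the final breath
#'       (L, single side).}
#'     \item{converged}{logical.}
#'     \item{duration}{length of the final breath (s); equals the forcing
#'       period at steady state.}
#'   }
#' @examples
#' \donttest{
#' sim <- simulate_airflow(airflow_params(), dt = 1e-3)
#' summary(sim)
#' }
#' @export
simulate_airflow <- function(p = airflow_params(), dt = 1e-4,
                             steady_tol = 1e-5, max_breaths = 200) {
  p <- as_airflow_params(p)
  dyn <- .dyn_cache(p)
  t0 <- 0
  X0 <- c(0, 0)
  # starting regime: probe the trajectory just ahead of t = 0 (at the rest
  # state the derivative is regime-independent) and classify the flow signs
  cls0 <- classify_region(X0[1], X0[2], p)
  dyn0 <- dyn[[cls0$region]]
  Xp <- .leg_state(dyn0, .leg_coef(dyn0, t0, X0), t0, t0 + 1e-7)[, 1]
  cls <- classify_region(Xp[1], Xp[2], p)
  region <- cls$region
  qT_sign <- cls$signs[["qT"]]

  breaths <- 0L
  converged <- FALSE
  net <- NA_real_
  while (breaths < max_breaths) {
    out <- .run_legs(p, dyn, t0, X0, region, qT_sign, n_switches = 4)
    t0 <- out$t; X0 <- out$X; region <- out$region; qT_sign <- out$qT_sign
    breaths <- breaths + 1L
    net <- out$net_qT
    if (abs(net) < steady_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("steady state not reached within ", max_breaths,
            " breaths (|net tracheal volume| = ", format(net), " L)")

  # align: advance to the next upward qT crossing (start of inspiration)
  al <- .run_legs(p, dyn, t0, X0, region, qT_sign, stop_at_qT_up = TRUE)
  # final breath with dense output, up to the following upward qT crossing
  fin <- .run_legs(p, dyn, al$t, al$X, al$region, qT_sign = 1,
                   stop_at_qT_up = TRUE, dt = dt)
  series <- .merge_series(fin$series)
  events <- fin$events
  # re-base time to the start of inspiration
  series$t <- series$t - al$t
  events$t <- events$t - al$t
  duration <- series$t[nrow(series)]
  events <- rbind(events[-nrow(events), , drop = FALSE],
                  data.frame(t = duration, kind = "breath_end"))
  # phase labels: INSP until the (interior) downward qT crossing, then EXP
  t_down <- events$t[events$kind == "qT_zero"]
  series$phase <- ifelse(series$t < t_down[1] - 1e-12, "INSP", "EXP")
  series$phase[nrow(series)] <- "EXP"

  structure(list(params = p, series = series, events = events,
                 breaths = breaths, net_tracheal_volume = fin$net_qT,
                 converged = converged, duration = duration, dt = dt,
                 steady_tol = steady_tol),
            class = "airflow_sim")
}

#' Fixed-step reference integrator
#'
#' A deliberately naive fixed-step fourth-order Runge-Kutta integrator in
#' which the flow regime is re-evaluated from the current flow signs at the
#' start of every step (no event location).  It is independent of the
#' event-driven closed-form propagation and serves as a cross-validation
#' reference in the test suite.
#'
#' @param p an \code{\link{airflow_params}} object.
#' @param dt fixed step size (s); must be at most \code{1e-4}.
#' @param t_end end time (s).
#' @param t0 start time (s).
#' @param x0 initial state \code{c(x1, x2)}.
#' @return A data frame with columns \code{t, x1, x2, region}.
#' @export
simulate_fixed_step <- function(p, dt = 1e-4, t_end, t0 = 0, x0 = c(0, 0)) {
  p <- as_airflow_params(p)
  stopifnot(dt <= 1e-4)
  A <- list("1" = system_matrix(regime_from_region("1"), p),
            "23" = system_matrix(regime_from_region("23"), p),
            "4" = system_matrix(regime_from_region("4"), p))
  amp <- p$P_amp * pi / p$T
  om <- 2 * pi / p$T
  n <- ceiling((t_end - t0) / dt)
  ts <- t0 + dt * (0:n)
  xs <- matrix(NA_real_, n + 1L, 2L)
  regions <- character(n + 1L)
  x <- x0
  for (i in 0:n) {
    reg <- classify_region(x[1], x[2], p)$region
    xs[i + 1L, ] <- x
    regions[i + 1L] <- reg
    if (i == n) break
    Ar <- A[[reg]]
    t <- ts[i + 1L]
    f <- function(tt, xx) drop(Ar %*% xx) + amp * sin(om * tt)
    k1 <- f(t, x)
    k2 <- f(t + dt / 2, x + dt / 2 * k1)
    k3 <- f(t + dt / 2, x + dt / 2 * k2)
    k4 <- f(t + dt, x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(t = ts, x1 = xs[, 1], x2 = xs[, 2], region = regions)
}

#' Inspiration/expiration intervals of a breath
#'
#' Partitions a simulated steady-state breath into inspiratory
#' (\code{qT > 0}) and expiratory (\code{qT < 0}) intervals using the
#' event-located zero crossings of the tracheal flow.
#'
#' @param sim an \code{\link{simulate_airflow}} result.
#' @return A data frame with columns \code{start}, \code{end}, \code{phase};
#'   empty when the breath has no tracheal flow.  More than two crossings per
#'   breath (a multi-phase breath) triggers a warning.
#' @export
detect_phase_boundaries <- function(sim) {
  ev <- sim$events
  tq <- ev$t[ev$kind == "qT_zero"]
  if (max(abs(sim$series$qT)) < 1e-12)
    return(data.frame(start = numeric(0), end = numeric(0),
                      phase = character(0)))
  if (length(tq) > 1L)
    warning("more than 2 tracheal-flow zero crossings in one breath: ",
            "multi-phase breath")
  bounds <- c(0, tq, sim$duration)
  # breath starts at an upward crossing: first interval is inspiration
  phases <- rep(c("INSP", "EXP"), length.out = length(bounds) - 1L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
             phase = phases)
}
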