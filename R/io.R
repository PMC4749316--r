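.config_keys <- c("P_atm", "R_trachea", "R_EPPB", "R_T", "R_P",
                  "R1_insp", "R2_insp", "R1_exp", "R2_exp",
                  "k_insp", "k_exp", "gamma", "C_tot", "C1", "C2",
                  "V1_res", "V2_res", "P_c", "P_amp", "T")

#' Read a model configuration file
#'
#' Configurations are flat JSON objects whose keys are the parameter symbols
#' accepted by \code{\link{airflow_params}} (e.g. \code{R_trachea},
#' \code{C_tot}, \code{gamma}, \code{P_amp}).  Unknown keys are rejected;
#' missing keys take their defaults; linked parameters are resolved on load.
#'
#' @param path path to a JSON file.
#' @return An \code{\link{airflow_params}} object.
#' @export
read_airflow_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg) && !is.null(names(cfg))) cfg <- as.list(cfg)
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "; allowed keys are: ", paste(.config_keys, collapse = ", "),
         call. = FALSE)
  do.call(airflow_params, cfg)
}

#' Write a resolved configuration
#'
#' Serialises a resolved parameter set back to the flat JSON configuration
#' dialect; reading it back reproduces the same resolved parameters.
#'
#' @param p an \code{\link{airflow_params}} object.
#' @param path output path.
#' @export
write_airflow_config <- function(p, path) {
  jsonlite::write_json(unclass(p)[.config_keys], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write simulation outputs
#'
#' Writes the sampled final breath as a CSV (columns \code{t, x1, x2, P1, P2,
#' qT_Lps, q1_Lps, q2_Lps, qP_Lps, PJ, V1_mL, V2_mL, region, phase}), the
#' located events as a companion CSV (\code{t, kind}), a summary JSON with
#' all breath metrics, and a run manifest (resolved parameters, solver
#' settings, convergence report, output paths).
#'
#' @param sim a \code{\link{simulate_airflow}} result.
#' @param dir output directory (created if needed).
#' @param whole_animal passed to \code{\link{breath_metrics}}.
#' @param prefix file name prefix.
#' @return Invisibly, the named vector of files written.
#' @export
write_simulation_outputs <- function(sim, dir, whole_animal = TRUE,
                                     prefix = "airflow") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- sim$series
  p <- sim$params
  ts <- data.frame(t = s$t, x1 = s$x1, x2 = s$x2,
                   P1 = s$x1 + p$P_atm, P2 = s$x2 + p$P_atm,
                   qT_Lps = s$qT, q1_Lps = s$q1, q2_Lps = s$q2,
                   qP_Lps = s$qP, PJ = s$PJ,
                   V1_mL = s$V1, V2_mL = s$V2,
                   region = s$region, phase = s$phase)
  files <- c(timeseries = file.path(dir, paste0(prefix, "_timeseries.csv")),
             events = file.path(dir, paste0(prefix, "_events.csv")),
             summary = file.path(dir, paste0(prefix, "_summary.json")),
             manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  utils::write.csv(ts, files[["timeseries"]], row.names = FALSE)
  utils::write.csv(sim$events, files[["events"]], row.names = FALSE)
  m <- breath_metrics(sim, whole_animal = whole_animal)
  jsonlite::write_json(unclass(m), files[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "aviflow",
    version = as.character(utils::packageVersion("aviflow")),
    parameters = unclass(p)[.config_keys],
    solver = list(dt = sim$dt, steady_tol = sim$steady_tol),
    convergence = list(converged = sim$converged, breaths = sim$breaths,
                       net_tracheal_volume_L = sim$net_tracheal_volume),
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, files[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Command-line entry points
#'
#' Thin wrappers used by the \code{aviflow} command-line script (see
#' \code{system.file("cli", "aviflow", package = "aviflow")}).
#' \code{cli_simulate} runs a steady-state simulation from a config file and
#' writes the time series, events, summary and manifest;
#' \code{cli_analyze} writes a JSON eigen/valving report for each regime;
#' \code{cli_sweep} runs a sweep specification and writes a CSV.
#'
#' @param config path to a JSON configuration (see
#'   \code{\link{read_airflow_config}}).
#' @param outdir output directory for \code{cli_simulate}.
#' @param dt,steady_tol,max_breaths solver settings.
#' @param single_side report single-side instead of whole-animal volumes.
#' @return \code{cli_simulate}: the written files (invisibly);
#'   \code{cli_analyze}: the report list (invisibly, after writing/printing);
#'   \code{cli_sweep}: the sweep data frame (invisibly).
#' @export
cli_simulate <- function(config, outdir, dt = 1e-4, steady_tol = 1e-5,
                         max_breaths = 200, single_side = FALSE) {
  p <- read_airflow_config(config)
  sim <- simulate_airflow(p, dt = dt, steady_tol = steady_tol,
                          max_breaths = max_breaths)
  files <- write_simulation_outputs(sim, outdir,
                                    whole_animal = !single_side)
  message(sprintf("breaths: %d, converged: %s, net tracheal volume: %.3e L",
                  sim$breaths, sim$converged, sim$net_tracheal_volume))
  if (!sim$converged)
    stop("simulation did not reach steady state", call. = FALSE)
  invisible(files)
}

#' @rdname cli_simulate
#' @param out output path (JSON for \code{cli_analyze}, CSV for
#'   \code{cli_sweep}); printed to stdout when \code{NULL}.
#' @export
cli_analyze <- function(config, out = NULL) {
  p <- read_airflow_config(config)
  regimes <- list(region1 = regime_from_region("1"),
                  region23 = regime_from_region("23"),
                  region4 = regime_from_region("4"))
  rep_one <- function(rg) {
    ea <- eigen_analysis(rg, p)
    list(lambda1 = ea$lambda1, lambda2 = ea$lambda2,
         V_fast = ea$V1_fast, V_slow = ea$V2_slow,
         trace = ea$trace, det = ea$determinant,
         discriminant = ea$discriminant, time_scale_s = ea$scale)
  }
  cert <- unidirectional_flow_condition(p)
  report <- c(lapply(regimes, rep_one),
              list(certificate = list(
                verdict = cert$verdict,
                effective_valves = cert$effective_valves,
                insp_gammaR1 = attr(cert$insp_condition, "gammaR1"),
                insp_R2 = attr(cert$insp_condition, "R2"),
                exp_gammaR1 = attr(cert$exp_condition, "gammaR1"),
                exp_R2 = attr(cert$exp_condition, "R2"))))
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(out)) cat(json, "\n") else writeLines(json, out)
  invisible(report)
}

#' @rdname cli_simulate
#' @param spec path to a JSON sweep specification with fields \code{param}
#'   (or \code{mode = "resistance_ratio"} with \code{ratios} and
#'   \code{total}), \code{values}, and optional \code{base} (a nested object
#'   of held parameter overrides), \code{dt}.
#' @export
cli_sweep <- function(spec, out) {
  sp <- jsonlite::read_json(spec, simplifyVector = TRUE)
  dt <- if (!is.null(sp$dt)) sp$dt else 1e-3
  base <- if (!is.null(sp$base)) as.list(sp$base) else list()
  res <- if (!is.null(sp$mode) && sp$mode == "resistance_ratio") {
    total <- if (!is.null(sp$total)) sp$total else 6
    resistance_ratio_sweep(sp$ratios, total = total, base = base, dt = dt)
  } else {
    if (is.null(sp$param) || is.null(sp$values))
      stop("sweep spec must contain 'param' and 'values' ",
           "(or mode = \"resistance_ratio\" with 'ratios')", call. = FALSE)
    run_sweep(sp$param, sp$values, base = base, dt = dt)
  }
  # fixed-format numbers so repeated runs are byte-identical
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) formatC(x, digits = 12,
                                                   format = "g"))
  utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}
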