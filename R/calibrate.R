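## Calibration of the geometric parameters the device drawings do not fix:
## membrane exchange areas, the effective no-flow channel path, and the
## tubing (loop) volume.

free_param_names <- c("exchange_area_POC", "exchange_area_LOC",
                      "channel_path_length", "loop_volume")

free_param_defaults <- function(device) {
  mi <- device$membrane_interfaces
  c(exchange_area_POC = mi$area_cm2[mi$from == "POC"][1],
    exchange_area_LOC = mi$area_cm2[mi$from == "LOC"][1],
    channel_path_length = device$no_flow_path_cm,
    loop_volume = device$compartments$volume_uL[
      device$compartments$id == "LOOP"][1])
}

free_param_bounds <- function() {
  list(lower = c(exchange_area_POC = 1e-3, exchange_area_LOC = 1e-3,
                 channel_path_length = 5e-3, loop_volume = 10),
       upper = c(exchange_area_POC = 5, exchange_area_LOC = 5,
                 channel_path_length = 0.5, loop_volume = 600))
}

#' Apply free geometric parameters to a device
#'
#' @param device A [mod_device()].
#' @param params Named numeric vector using any of `exchange_area_POC`,
#'   `exchange_area_LOC` (cm^2), `channel_path_length` (cm), `loop_volume`
#'   (uL).
#' @return The modified device.
#' @export
set_free_params <- function(device, params) {
  bad <- setdiff(names(params), free_param_names)
  if (length(bad)) {
    abort(sprintf("unknown free parameter(s): %s", paste(bad, collapse = ", ")),
          class = "organflux_precondition_error")
  }
  for (nm in names(params)) {
    val <- unname(params[[nm]])
    if (nm == "exchange_area_POC") {
      device$membrane_interfaces$area_cm2[
        device$membrane_interfaces$from == "POC"] <- val
    } else if (nm == "exchange_area_LOC") {
      device$membrane_interfaces$area_cm2[
        device$membrane_interfaces$from == "LOC"] <- val
    } else if (nm == "channel_path_length") {
      device$no_flow_path_cm <- val
    } else if (nm == "loop_volume") {
      device$compartments$volume_uL[device$compartments$id == "LOOP"] <- val
    }
  }
  device
}

# Relative residuals with a floor so zero observations do not explode.
relative_residuals <- function(sim, obs) {
  floor <- 1e-3 * max(abs(obs), 1e-12)
  (sim - obs) / pmax(abs(obs), floor)
}

#' Calibrate free geometry against an observed tracer time series
#'
#' Least-squares fit (Levenberg-Marquardt, bounded) of the selected free
#' parameters, minimising the sum of squared relative residuals between
#' simulated and observed concentrations. Deterministic for a fixed starting
#' point (the device's current values) and bounds. Parameters whose
#' perturbation leaves the simulated observations essentially unchanged are
#' reported as non-identifiable in the identifiability notes rather than
#' silently fixed.
#'
#' @param device_template A [mod_device()] providing everything except the
#'   free parameters.
#' @param observed Tibble with columns `time_s`, `compartment`, `species`,
#'   `concentration` and optionally `flow` (logical, default `TRUE`) and
#'   `replicate`. At least 3 timepoints for one species/condition.
#' @param species A [mod_species()] describing what was loaded where (the
#'   observed table records responses, not loadings).
#' @param free_params Character subset of `exchange_area_POC`,
#'   `exchange_area_LOC`, `channel_path_length`, `loop_volume`.
#' @param bounds Optional list with named vectors `lower`, `upper`.
#' @return A `calibration_report`: fitted parameter tibble, residual norm,
#'   identifiability notes, and the calibrated device.
#' @export
calibrate_geometry <- function(device_template, observed, species,
                               free_params = c("exchange_area_POC",
                                               "channel_path_length"),
                               bounds = NULL) {
  stopifnot(inherits(device_template, "mod_device"))
  observed <- as_tibble(observed)
  if (!nrow(observed)) {
    abort("observed table is empty", class = "organflux_precondition_error")
  }
  req <- c("time_s", "compartment", "species", "concentration")
  if (!all(req %in% names(observed))) {
    abort(sprintf("observed needs columns: %s", paste(req, collapse = ", ")),
          class = "organflux_precondition_error")
  }
  if (!"flow" %in% names(observed)) observed$flow <- TRUE
  if (length(unique(observed$time_s[observed$time_s > 0])) < 3) {
    abort("observed must cover at least 3 positive timepoints",
          class = "organflux_precondition_error")
  }
  bad <- setdiff(free_params, free_param_names)
  if (length(bad)) {
    abort(sprintf("unknown free parameter(s): %s", paste(bad, collapse = ", ")),
          class = "organflux_precondition_error")
  }
  # average replicates: the model predicts the mean response
  obs <- observed %>%
    group_by(.data$time_s, .data$compartment, .data$flow) %>%
    summarise(concentration = mean(.data$concentration), .groups = "drop")
  sim_fun <- function(device) {
    out <- numeric(nrow(obs))
    for (fl in unique(obs$flow)) {
      sel <- obs$flow == fl
      times <- sort(unique(obs$time_s[sel]))
      tr <- simulate_transport(device, species, flow_enabled = fl,
                               duration_s = max(times),
                               output_times = times)
      for (i in which(sel)) {
        out[i] <- result_concentration(tr, obs$compartment[i], obs$time_s[i])
      }
    }
    out
  }
  run_objective(device_template, free_params, bounds,
                sim_fun = sim_fun, obs_values = obs$concentration,
                observed = obs)
}

#' Calibrate free geometry against transport summary metrics
#'
#' Same machinery as [calibrate_geometry()], but the observations are
#' summary metrics (percent transferred, fold enhancement) such as the
#' reported values in [reported_transport_metrics()], rather than raw
#' concentration curves.
#'
#' @param device_template A [mod_device()] (from [load_config()], so species
#'   definitions are available).
#' @param metrics Tibble as returned by [reported_transport_metrics()]:
#'   columns `metric`, `species`, `source`, `targets` (ids separated by
#'   `;`), `compartment`, `flow`, `load_conc`, `time_s`, `value`.
#' @param free_params,bounds As in [calibrate_geometry()].
#' @return A `calibration_report`.
#' @export
#' @examples
#' \donttest{
#' dev <- mod_device_default()
#' reported <- reported_transport_metrics()
#' rep <- calibrate_transport_metrics(dev,
#'   dplyr::filter(reported, species == "dextran4"),
#'   free_params = c("exchange_area_POC", "exchange_area_LOC",
#'                   "channel_path_length"))
#' rep$params
#' }
calibrate_transport_metrics <- function(device_template, metrics,
                                        free_params = c("exchange_area_POC",
                                                        "exchange_area_LOC",
                                                        "channel_path_length"),
                                        bounds = NULL) {
  stopifnot(inherits(device_template, "mod_device"))
  metrics <- as_tibble(metrics)
  if (!nrow(metrics)) {
    abort("metrics table is empty", class = "organflux_precondition_error")
  }
  sim_fun <- function(device) evaluate_transport_metrics(device, metrics)$model_value
  run_objective(device_template, free_params, bounds,
                sim_fun = sim_fun, obs_values = metrics$value,
                observed = metrics)
}

#' Evaluate transport metrics under a device model
#'
#' @param device A [mod_device()] with a species table.
#' @param metrics Metric specification tibble (see
#'   [calibrate_transport_metrics()]).
#' @return `metrics` with a `model_value` column appended.
#' @export
evaluate_transport_metrics <- function(device, metrics) {
  metrics <- as_tibble(metrics)
  runs <- list()
  get_run <- function(sp_name, source, load_conc, fl, t_need) {
    key <- paste(sp_name, source, load_conc, fl, sep = "|")
    if (is.null(runs[[key]]) ||
        !all(t_need %in% runs[[key]]$time_grid)) {
      loaded <- strsplit(source, ";")[[1]]
      sp <- tracer_species(device, sp_name, loaded, load_conc)
      times <- sort(unique(c(t_need, if (!is.null(runs[[key]]))
        runs[[key]]$time_grid)))
      runs[[key]] <<- simulate_transport(device, sp, flow_enabled = fl,
                                         duration_s = max(times),
                                         output_times = times)
    }
    runs[[key]]
  }
  model_value <- numeric(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    row <- metrics[i, ]
    if (row$metric == "percent_transferred") {
      tr <- get_run(row$species, row$source, row$load_conc, row$flow,
                    row$time_s)
      model_value[i] <- percent_transferred(
        tr, strsplit(row$source, ";")[[1]][1],
        strsplit(row$targets, ";")[[1]], row$time_s)
    } else if (row$metric == "fold_enhancement") {
      tr_f <- get_run(row$species, row$source, row$load_conc, TRUE, row$time_s)
      tr_n <- get_run(row$species, row$source, row$load_conc, FALSE, row$time_s)
      model_value[i] <- fold_enhancement(tr_f, tr_n, row$compartment,
                                         device_species(device, row$species)$name,
                                         row$time_s)
    } else {
      abort(sprintf("unknown metric '%s'", row$metric),
            class = "organflux_precondition_error")
    }
  }
  metrics$model_value <- model_value
  metrics
}

# Shared bounded LM driver + identifiability screen.
run_objective <- function(device_template, free_params, bounds, sim_fun,
                          obs_values, observed) {
  defaults <- free_param_defaults(device_template)
  std_bounds <- free_param_bounds()
  lower <- std_bounds$lower[free_params]
  upper <- std_bounds$upper[free_params]
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  start <- pmin(pmax(defaults[free_params], lower), upper)
  resid_fn <- function(p) {
    dev <- set_free_params(device_template, setNames(p, free_params))
    r <- relative_residuals(sim_fun(dev), obs_values)
    r[!is.finite(r)] <- 1e3
    r
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12,
                              epsfcn = 1e-8))
  fitted <- setNames(as.numeric(fit$par), free_params)
  # identifiability: relative response of the simulated observations to a
  # 5% parameter perturbation
  base_sim <- sim_fun(set_free_params(device_template, fitted))
  scale <- max(abs(obs_values), 1e-12)
  sens <- vapply(free_params, function(nm) {
    pert <- fitted
    pert[nm] <- pert[nm] * 1.05
    max(abs(sim_fun(set_free_params(device_template, pert)) - base_sim)) / scale
  }, numeric(1))
  report <- list(
    params = tibble(param = free_params, value = unname(fitted),
                    lower = unname(lower), upper = unname(upper),
                    at_bound = unname(fitted <= lower * (1 + 1e-6) |
                                      fitted >= upper * (1 - 1e-6))),
    residual_norm = sqrt(sum(fit$fvec^2)),
    identifiability = tibble(
      param = free_params, sensitivity = unname(sens),
      identifiable = unname(sens > 1e-4),
      note = ifelse(sens > 1e-4, "informative",
                    "flat sensitivity: value reflects the default/bound, not the data")),
    observed = observed,
    device = set_free_params(device_template, fitted),
    converged = fit$info %in% 1:4
  )
  if (!is.finite(report$residual_norm)) {
    abort("calibration residual norm is not finite",
          class = "organflux_solver_error")
  }
  class(report) <- "calibration_report"
  report
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report> residual norm:",
      format(x$residual_norm, digits = 4), "\n")
  print(x$params)
  ni <- x$identifiability[!x$identifiability$identifiable, ]
  if (nrow(ni)) {
    cat("non-identifiable:", paste(ni$param, collapse = ", "), "\n")
  }
  invisible(x)
}
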