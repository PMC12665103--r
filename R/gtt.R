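## Minimal glucose-insulin feedback model layered on the transport network.
##
## Insulin is secreted by the pancreatic organoids (POC) with a biphasic
## threshold-linear law, transported through the device as a 4 kDa-sized
## species, turned over first-order toward its basal level, and drives
## mass-action glucose clearance by the liver organoids (LOC).

#' Glucose-insulin model parameters
#'
#' @param basal_insulin Basal insulin concentration in ug/L; insulin relaxes
#'   toward it at `insulin_turnover`.
#' @param first_phase_amplitude First-phase secretion gain, ug/(L h) per mM
#'   of POC glucose above threshold; decays with `first_phase_decay`.
#' @param first_phase_decay Decay rate of the first secretion phase, 1/h.
#' @param sustained_rate Sustained secretion gain, ug/(L h) per mM above
#'   threshold.
#' @param glucose_threshold Secretion threshold theta in mM; must lie in
#'   (2.8, 20), the bracket of the GSIS protocol concentrations.
#' @param uptake_rate Insulin-dependent hepatic clearance, 1/(h (ug/L)):
#'   glucose is removed in the LOC at `uptake_rate * I_LOC * G_LOC`.
#' @param insulin_turnover First-order insulin relaxation rate, 1/h.
#' @param pa_secretion_factor,pa_uptake_factor Multiplicative palmitate
#'   impairment factors in (0, 1] applied to secretion and uptake.
#' @param metformin_uptake_boost,metformin_secretion_boost Multiplicative
#'   metformin factors >= 1 (hepatic uptake restoration via AMPK; secretion
#'   support via aquaporin-7), applied on top of the palmitate factors.
#' @return An object of class `gi_params`.
#' @export
#' @examples
#' gi_params(basal_insulin = 22)
gi_params <- function(basal_insulin = 22.5,
                      first_phase_amplitude = 1.0,
                      first_phase_decay = 1.5,
                      sustained_rate = 1.8,
                      glucose_threshold = 5.5,
                      uptake_rate = 0.075,
                      insulin_turnover = 0.3,
                      pa_secretion_factor = 1,
                      pa_uptake_factor = 0.02,
                      metformin_uptake_boost = 40,
                      metformin_secretion_boost = 1) {
  p <- list(basal_insulin = basal_insulin,
            first_phase_amplitude = first_phase_amplitude,
            first_phase_decay = first_phase_decay,
            sustained_rate = sustained_rate,
            glucose_threshold = glucose_threshold,
            uptake_rate = uptake_rate,
            insulin_turnover = insulin_turnover,
            pa_secretion_factor = pa_secretion_factor,
            pa_uptake_factor = pa_uptake_factor,
            metformin_uptake_boost = metformin_uptake_boost,
            metformin_secretion_boost = metformin_secretion_boost)
  validate_gi_params(p)
  structure(p, class = "gi_params")
}

validate_gi_params <- function(p) {
  rates <- c("basal_insulin", "first_phase_amplitude", "first_phase_decay",
             "sustained_rate", "uptake_rate", "insulin_turnover")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0) {
      abort(sprintf("%s must be a rate >= 0", nm),
            class = "organflux_param_error")
    }
  }
  if (p$glucose_threshold <= 2.8 || p$glucose_threshold >= 20) {
    abort("glucose_threshold must lie within (2.8, 20) mM",
          class = "organflux_param_error")
  }
  for (nm in c("pa_secretion_factor", "pa_uptake_factor")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) {
      abort(sprintf("%s must lie in (0, 1]", nm),
            class = "organflux_param_error")
    }
  }
  for (nm in c("metformin_uptake_boost", "metformin_secretion_boost")) {
    if (p[[nm]] < 1) {
      abort(sprintf("%s must be >= 1", nm), class = "organflux_param_error")
    }
  }
  invisible(p)
}

condition_factors <- function(params, condition) {
  switch(condition,
    control = c(fs = 1, fu = 1),
    pa = c(fs = params$pa_secretion_factor, fu = params$pa_uptake_factor),
    pa_metformin = c(
      fs = min(params$pa_secretion_factor * params$metformin_secretion_boost, 1),
      fu = params$pa_uptake_factor * params$metformin_uptake_boost),
    abort(sprintf("unknown condition '%s'", condition),
          class = "organflux_param_error"))
}

#' Simulate an in vitro glucose tolerance test
#'
#' A bolus of glucose (default 13 mM, mimicking postprandial hyperglycemia)
#' replaces the circulating media (CC + tubing loop); the organoid chambers
#' start at the baseline media glucose. Insulin secretion responds to POC
#' glucose above threshold with a decaying first phase plus a sustained
#' phase; insulin travels through the device with the diffusivity of its
#' 4 kDa size surrogate; the liver chamber clears glucose at
#' `uptake_rate * I_LOC * G_LOC`.
#'
#' @param device A [mod_device()] from [load_config()] (flow on).
#' @param params A [gi_params()].
#' @param condition `"control"`, `"pa"` or `"pa_metformin"`.
#' @param dose_mM Injected glucose concentration in mM (0 = no injection,
#'   the circulating media stays at baseline).
#' @param duration_h Simulated duration in hours.
#' @param baseline_glucose_mM Media glucose before injection (default
#'   5.5 mM, the culture perfusate).
#' @param output_times_h Extra report times in hours (the trajectory is
#'   always sampled every 0.25 h).
#' @return A `gtt_result`: `trajectories` (tibble `time_h`, `compartment`,
#'   `variable`, `value`), `glucose_trajectory` / `insulin_trajectory`
#'   (sampled in the CC, where the assay drew its samples), `peak_insulin`,
#'   `auc_glucose` (0 to `duration_h`), `auc_insulin_sustained` (4-24 h),
#'   `condition`, and `params`.
#' @export
#' @examples
#' dev <- mod_device_default()
#' res <- simulate_gtt(dev, gi_params(), "control", dose_mM = 13,
#'                     duration_h = 6)
#' res$peak_insulin
simulate_gtt <- function(device, params, condition = "control", dose_mM = 13,
                         duration_h = 24, baseline_glucose_mM = 5.5,
                         output_times_h = NULL) {
  stopifnot(inherits(device, "mod_device"))
  if (!inherits(params, "gi_params")) params <- do.call(gi_params, params)
  validate_gi_params(params)
  if (dose_mM < 0) {
    abort("dose must be >= 0", class = "organflux_precondition_error")
  }
  fac <- condition_factors(params, condition)
  ids <- device$compartments$id
  n <- length(ids)
  glc <- device_species(device, "glucose")
  ins <- device_species(device, "insulin")
  # per-hour rate matrices for the two transported variables
  a_g <- transport_matrix(device, glc$diffusivity_m2_s, TRUE)$a * 3600
  a_i <- transport_matrix(device, ins$diffusivity_m2_s, TRUE)$a * 3600
  i_poc <- match("POC", ids); i_loc <- match("LOC", ids)
  circulating <- ids[device$compartments$role != "organoid-chamber"]
  g0 <- setNames(rep(baseline_glucose_mM, n), ids)
  if (dose_mM > 0) g0[circulating] <- dose_mM
  y0 <- c(g0, setNames(rep(params$basal_insulin, n), paste0("I_", ids)))
  th <- params$glucose_threshold
  rhs <- function(t, y, p) {
    g <- pmax(y[1:n], 0); i <- pmax(y[(n + 1):(2 * n)], 0)
    dg <- as.vector(a_g %*% g)
    di <- as.vector(a_i %*% i)
    gp <- max(g[i_poc] - th, 0)
    di[i_poc] <- di[i_poc] + fac[["fs"]] *
      (params$first_phase_amplitude * gp * exp(-params$first_phase_decay * t) +
         params$sustained_rate * gp)
    di <- di + params$insulin_turnover * (params$basal_insulin - i)
    dg[i_loc] <- dg[i_loc] -
      fac[["fu"]] * params$uptake_rate * i[i_loc] * g[i_loc]
    list(c(dg, di))
  }
  times <- sort(unique(c(seq(0, duration_h, by = 0.25), output_times_h)))
  if (any(times < 0 | times > duration_h)) {
    abort("output times must lie within the simulated duration",
          class = "organflux_precondition_error")
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    abort("glucose-insulin integration failed",
          class = "organflux_solver_error")
  }
  traj <- as_tibble(as.data.frame(sol)) %>%
    rename(time_h = "time") %>%
    tidyr::pivot_longer(-"time_h", names_to = "state", values_to = "value") %>%
    mutate(variable = ifelse(startsWith(.data$state, "I_"),
                             "insulin", "glucose"),
           compartment = sub("^I_", "", .data$state)) %>%
    select("time_h", "compartment", "variable", "value")
  g_cc <- traj %>% filter(.data$compartment == "CC",
                          .data$variable == "glucose")
  i_cc <- traj %>% filter(.data$compartment == "CC",
                          .data$variable == "insulin")
  structure(list(
    trajectories = traj,
    glucose_trajectory = g_cc %>% select("time_h", "value"),
    insulin_trajectory = i_cc %>% select("time_h", "value"),
    peak_insulin = max(i_cc$value),
    auc_glucose = trajectory_auc(g_cc %>% select("time_h", "value"),
                                 0, duration_h),
    auc_insulin_sustained = if (duration_h >= 24)
      trajectory_auc(i_cc %>% select("time_h", "value"), 4, 24) else NA_real_,
    condition = condition, dose_mM = dose_mM, params = params
  ), class = "gtt_result")
}

#' @export
print.gtt_result <- function(x, ...) {
  cat("<gtt_result>", x$condition, "| dose", x$dose_mM, "mM\n")
  cat(sprintf("peak insulin %.2f ug/L | glucose AUC %.1f mM h\n",
              x$peak_insulin, x$auc_glucose))
  invisible(x)
}

#' Trapezoidal area under a trajectory
#'
#' @param traj Two-column table (time, value) — e.g.
#'   `gtt_result$glucose_trajectory`.
#' @param t_start,t_end Window bounds (same time units as `traj`); must lie
#'   within the stored grid, with `t_start < t_end`. Values at the window
#'   edges are obtained by linear interpolation.
#' @param reference Optional scalar to normalise by (e.g. the control
#'   condition's AUC).
#' @return The (optionally normalised) trapezoidal AUC.
#' @export
#' @examples
#' trajectory_auc(data.frame(t = 0:10, v = rep(2, 11)), 0, 10) # 20
trajectory_auc <- function(traj, t_start, t_end, reference = NULL) {
  traj <- as.data.frame(traj)
  t <- traj[[1]]; v <- traj[[2]]
  if (t_start >= t_end) {
    abort("empty AUC window: t_start must be < t_end",
          class = "organflux_precondition_error")
  }
  if (t_start < min(t) || t_end > max(t)) {
    abort("AUC window outside trajectory span",
          class = "organflux_precondition_error")
  }
  grid <- sort(unique(c(t[t > t_start & t < t_end], t_start, t_end)))
  vals <- approx(t, v, xout = grid)$y
  auc <- sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2)
  if (!is.null(reference)) auc <- auc / reference
  auc
}

#' Glucose-stimulated insulin secretion protocol
#'
#' Reproduces the off-device assay: organoids in a static well are starved
#' for 1 h at 2.8 mM glucose, then stimulated for 1 h at 20 mM, the cycle
#' repeated. Released insulin per phase integrates the basal release
#' (`insulin_turnover * basal_insulin`) plus the stimulated secretion law;
#' the stimulation index is the high/low ratio.
#'
#' @param params A [gi_params()].
#' @param condition `"control"`, `"pa"` or `"pa_metformin"`.
#' @param cycles Number of low/high cycles (>= 1).
#' @param low_mM,high_mM Starvation and stimulation glucose (defaults 2.8
#'   and 20 mM).
#' @param phase_h Duration of each phase in hours.
#' @return A `gsis_result` tibble: `cycle`, `insulin_low`, `insulin_high`
#'   (ug/L released per phase) and `stimulation_index`.
#' @export
#' @examples
#' gsis_protocol(gi_params(), "control", cycles = 3)
gsis_protocol <- function(params, condition = "control", cycles = 3,
                          low_mM = 2.8, high_mM = 20, phase_h = 1) {
  if (!inherits(params, "gi_params")) params <- do.call(gi_params, params)
  validate_gi_params(params)
  if (cycles < 1) {
    abort("cycles must be >= 1", class = "organflux_precondition_error")
  }
  fac <- condition_factors(params, condition)
  basal_release <- params$insulin_turnover * params$basal_insulin * phase_h
  phase_release <- function(g) {
    gp <- max(g - params$glucose_threshold, 0)
    lam <- params$first_phase_decay
    first <- if (lam > 0) {
      params$first_phase_amplitude * gp * (1 - exp(-lam * phase_h)) / lam
    } else {
      params$first_phase_amplitude * gp * phase_h
    }
    basal_release + fac[["fs"]] *
      (first + params$sustained_rate * gp * phase_h)
  }
  out <- tibble(
    cycle = seq_len(cycles),
    insulin_low = phase_release(low_mM),
    insulin_high = phase_release(high_mM)
  ) %>% mutate(stimulation_index = .data$insulin_high / .data$insulin_low)
  class(out) <- c("gsis_result", class(out))
  out
}
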