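## Weighted least-squares fitting of the glucose-insulin model to sparse
## observed GTT series. Parameters are shared across conditions; palmitate
## (and metformin) enter only through their multiplicative condition factors.

gtt_free_defaults <- function(conditions) {
  free <- c("basal_insulin", "first_phase_amplitude", "sustained_rate",
            "uptake_rate")
  if (any(conditions %in% c("pa", "pa_metformin"))) {
    free <- c(free, "pa_secretion_factor", "pa_uptake_factor")
  }
  if ("pa_metformin" %in% conditions) {
    free <- c(free, "metformin_uptake_boost")
  }
  free
}

gtt_bounds <- function() {
  list(lower = c(basal_insulin = 1, first_phase_amplitude = 0,
                 sustained_rate = 0, uptake_rate = 1e-4,
                 pa_secretion_factor = 0.01, pa_uptake_factor = 1e-4,
                 metformin_uptake_boost = 1),
       upper = c(basal_insulin = 50, first_phase_amplitude = 50,
                 sustained_rate = 20, uptake_rate = 1,
                 pa_secretion_factor = 1, pa_uptake_factor = 1,
                 metformin_uptake_boost = 500))
}

gtt_starts <- function(free) {
  full <- list(
    c(basal_insulin = 21, first_phase_amplitude = 2, sustained_rate = 1,
      uptake_rate = 0.02, pa_secretion_factor = 0.7, pa_uptake_factor = 0.1,
      metformin_uptake_boost = 20),
    c(basal_insulin = 22, first_phase_amplitude = 5, sustained_rate = 2,
      uptake_rate = 0.05, pa_secretion_factor = 0.9, pa_uptake_factor = 0.05,
      metformin_uptake_boost = 50),
    c(basal_insulin = 20.5, first_phase_amplitude = 0.5, sustained_rate = 0.5,
      uptake_rate = 0.1, pa_secretion_factor = 0.5, pa_uptake_factor = 0.3,
      metformin_uptake_boost = 100)
  )
  lapply(full, function(s) s[free])
}

apply_free <- function(base, values) {
  p <- unclass(base)
  p[names(values)] <- as.list(unname(as.numeric(values)))
  do.call(gi_params, p)
}

#' Fit glucose-insulin parameters to observed GTT series
#'
#' Weighted least squares (weights `1/sd` when SDs are supplied, else
#' uniform) over all conditions jointly: kinetic parameters are shared and
#' the palmitate/metformin condition factors are fitted only when the
#' corresponding condition is observed. Deterministic: a fixed list of
#' starting points is tried and the best bounded Levenberg-Marquardt
#' solution returned. Refuses under-determined problems (fewer observations
#' than free parameters).
#'
#' @param observed Tibble with columns `condition` (`control`, `pa`,
#'   `pa_metformin`), `variable` (`glucose`/`insulin`), `time_h`, `value`,
#'   optional `sd` — e.g. [reported_gtt_observations()].
#' @param device A [mod_device()].
#' @param params_init A [gi_params()] providing the fixed parameters
#'   (threshold, decay, turnover) and defaults for the free ones.
#' @param free Character vector of parameters to fit; defaults depend on
#'   the conditions present.
#' @param dose_mM,duration_h GTT protocol passed to [simulate_gtt()].
#' @param bounds Optional list with named `lower`/`upper` overrides.
#' @param starts Optional list of named start vectors (overrides the fixed
#'   multistart list).
#' @return A `gtt_fit`: fitted [gi_params()], per-condition factor table,
#'   residual table and norm.
#' @export
#' @examples
#' \donttest{
#' dev <- mod_device_default()
#' fit <- fit_gtt_params(reported_gtt_observations(), dev)
#' tidy(fit)
#' }
fit_gtt_params <- function(observed, device, params_init = gi_params(),
                           free = NULL, dose_mM = 13, duration_h = 24,
                           bounds = NULL, starts = NULL) {
  observed <- as_tibble(observed)
  req <- c("condition", "variable", "time_h", "value")
  missing <- setdiff(req, names(observed))
  if (length(missing)) {
    abort(sprintf("observed needs column(s) %s",
                  paste(missing, collapse = ", ")),
          class = "organflux_precondition_error")
  }
  if (!"sd" %in% names(observed)) observed$sd <- NA_real_
  conditions <- unique(observed$condition)
  bad <- setdiff(conditions, c("control", "pa", "pa_metformin"))
  if (length(bad)) {
    abort(sprintf("unknown condition(s) %s", paste(bad, collapse = ", ")),
          class = "organflux_precondition_error")
  }
  if (is.null(free)) free <- gtt_free_defaults(conditions)
  if (nrow(observed) < length(free)) {
    abort(sprintf(
      "under-determined fit: %d observation(s) for %d free parameter(s); supply more data or fix parameters",
      nrow(observed), length(free)),
      class = "organflux_underdetermined")
  }
  if (any(observed$time_h > duration_h)) {
    abort("observed times exceed the simulated duration",
          class = "organflux_precondition_error")
  }
  b <- gtt_bounds()
  lower <- b$lower[free]; upper <- b$upper[free]
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  weights <- ifelse(is.finite(observed$sd) & observed$sd > 0,
                    1 / observed$sd, 1)
  predict_obs <- function(params) {
    out <- numeric(nrow(observed))
    for (cond in conditions) {
      sel <- observed$condition == cond
      res <- simulate_gtt(device, params, cond, dose_mM = dose_mM,
                          duration_h = duration_h,
                          output_times_h = sort(unique(observed$time_h[sel])))
      for (i in which(sel)) {
        traj <- if (observed$variable[i] == "glucose") {
          res$glucose_trajectory
        } else {
          res$insulin_trajectory
        }
        j <- which(abs(traj$time_h - observed$time_h[i]) < 1e-9)
        out[i] <- traj$value[j[1]]
      }
    }
    out
  }
  resid_fn <- function(p) {
    params <- apply_free(params_init, setNames(p, free))
    r <- (predict_obs(params) - observed$value) * weights
    r[!is.finite(r)] <- 1e3
    r
  }
  if (is.null(starts)) starts <- gtt_starts(free)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s[free], lower), upper)
    fit <- minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower,
                              upper = upper,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 300, ftol = 1e-12, ptol = 1e-12,
                                epsfcn = 1e-8))
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  fitted_params <- apply_free(params_init, setNames(best$par, free))
  fitted_obs <- predict_obs(fitted_params)
  residuals <- observed %>%
    mutate(fitted = fitted_obs, weight = weights,
           residual = (fitted_obs - .data$value) * weights)
  factors <- dplyr::bind_rows(lapply(conditions, function(cond) {
    f <- condition_factors(fitted_params, cond)
    tibble(condition = cond, secretion_factor = f[["fs"]],
           uptake_factor = f[["fu"]])
  }))
  structure(list(params = fitted_params,
                 free = free,
                 estimates = setNames(as.numeric(best$par), free),
                 condition_factors = factors,
                 residuals = residuals,
                 residual_norm = sqrt(sum(best$fvec^2)),
                 converged = best$info %in% 1:4,
                 n_obs = nrow(observed)),
            class = "gtt_fit")
}

#' @export
print.gtt_fit <- function(x, ...) {
  cat("<gtt_fit>", x$n_obs, "observations,", length(x$free),
      "free parameters | weighted residual norm",
      format(x$residual_norm, digits = 4), "\n")
  print(tidy(x))
  invisible(x)
}
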