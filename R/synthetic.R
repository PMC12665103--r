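## Synthetic-data generators: noisy tracer assays and GTT series with the
## statistical structure the estimators assume, so every stage is testable
## without any experimental download.

#' Measurement-noise model
#'
#' @param kind `"multiplicative-gaussian"` (value * (1 + cv * z)) or
#'   `"additive-gaussian"` (value + sd * z).
#' @param cv_or_sd Coefficient of variation (multiplicative) or standard
#'   deviation in data units (additive). The defaults used by the
#'   generators mimic the dispersion of the reported replicate read-outs
#'   (~13% for tracer assays, ~4% for insulin).
#' @param seed Integer RNG seed; the same seed and inputs give identical
#'   output.
#' @param floor_at_zero Clip negative draws to 0 (concentrations are
#'   non-negative); the number of floored values is recorded on the output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-gaussian",
                                 "additive-gaussian"),
                        cv_or_sd = 0.13, seed = 1L, floor_at_zero = TRUE) {
  kind <- match.arg(kind)
  if (cv_or_sd < 0) {
    abort("cv_or_sd must be >= 0", class = "organflux_precondition_error")
  }
  structure(list(kind = kind, cv_or_sd = cv_or_sd, seed = as.integer(seed),
                 floor_at_zero = isTRUE(floor_at_zero)),
            class = "noise_model")
}

with_noise_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

apply_noise <- function(values, noise) {
  z <- stats::rnorm(length(values))
  noisy <- switch(noise$kind,
    "multiplicative-gaussian" = values * (1 + noise$cv_or_sd * z),
    "additive-gaussian" = values + noise$cv_or_sd * z)
  n_floored <- 0L
  if (noise$floor_at_zero) {
    n_floored <- sum(noisy < 0)
    noisy[noisy < 0] <- 0
  }
  list(values = noisy, n_floored = n_floored)
}

#' Tracer assay design
#'
#' @param species Species name or surrogate alias.
#' @param loaded_compartment Compartment id(s) carrying the initial load.
#' @param load_concentration Initial concentration in the species' units.
#' @param sampled_compartments Compartments from which aliquots are drawn.
#' @param sample_times_s Increasing sampling times in seconds.
#' @param flow_enabled Logical.
#' @param replicates Number of replicate devices (>= 1).
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(species, loaded_compartment, load_concentration,
                         sampled_compartments, sample_times_s,
                         flow_enabled = TRUE, replicates = 3) {
  if (is.unsorted(sample_times_s, strictly = TRUE)) {
    abort("sample_times_s must be strictly increasing",
          class = "organflux_precondition_error")
  }
  if (replicates < 1) {
    abort("replicates must be >= 1", class = "organflux_precondition_error")
  }
  structure(list(species = species,
                 loaded_compartment = loaded_compartment,
                 load_concentration = load_concentration,
                 sampled_compartments = sampled_compartments,
                 sample_times_s = sample_times_s,
                 flow_enabled = isTRUE(flow_enabled),
                 replicates = as.integer(replicates)),
            class = "assay_design")
}

#' Generate a synthetic tracer assay
#'
#' Simulates the assay with [simulate_transport()] and overlays replicate
#' measurement noise. The output follows the observed-data CSV schema of
#' [read_timeseries()].
#'
#' @param device A [mod_device()].
#' @param design An [assay_design()].
#' @param noise A [noise_model()] (tracer default: multiplicative, CV 13%).
#' @return Tibble `time_s`, `compartment`, `species`, `concentration`,
#'   `units`, `replicate`, `flow`, with attribute `n_floored`.
#' @export
#' @examples
#' dev <- mod_device_default()
#' des <- assay_design("dextran4", "POC", 1, c("CC", "LOC"),
#'                     c(1800, 3600, 7200, 10800))
#' tab <- generate_tracer_assay(dev, des, noise_model(seed = 7))
#' head(tab)
generate_tracer_assay <- function(device, design,
                                  noise = noise_model(cv_or_sd = 0.13)) {
  stopifnot(inherits(device, "mod_device"), inherits(design, "assay_design"),
            inherits(noise, "noise_model"))
  sp <- tracer_species(device, design$species, design$loaded_compartment,
                       design$load_concentration)
  tr <- simulate_transport(device, sp, flow_enabled = design$flow_enabled,
                           duration_s = max(design$sample_times_s),
                           output_times = design$sample_times_s)
  clean <- tr$data %>%
    filter(.data$compartment %in% design$sampled_compartments,
           .data$time_s %in% design$sample_times_s)
  out <- with_noise_seed(noise$seed, {
    tabs <- lapply(seq_len(design$replicates), function(r) {
      noisy <- apply_noise(clean$concentration, noise)
      clean %>% mutate(concentration = noisy$values, replicate = r,
                       n_floored = noisy$n_floored)
    })
    bind_rows(tabs)
  })
  n_floored <- sum(out$n_floored[!duplicated(out$replicate)])
  out <- out %>% select(-"n_floored") %>%
    mutate(flow = design$flow_enabled) %>%
    arrange(.data$replicate, .data$compartment, .data$time_s)
  attr(out, "n_floored") <- n_floored
  out
}

#' Generate a synthetic GTT observation table
#'
#' Simulates [simulate_gtt()] under a condition and samples the CC glucose
#' and insulin trajectories at the requested times with measurement noise.
#' With `replicates > 1`, replicate draws are aggregated to mean and SD, so
#' the output follows the observed-data schema of [read_gtt_observations()]
#' and can be fed straight into [fit_gtt_params()].
#'
#' @param device A [mod_device()].
#' @param params A [gi_params()].
#' @param condition `"control"`, `"pa"` or `"pa_metformin"`.
#' @param noise A [noise_model()] (insulin-like default: CV 4%).
#' @param sample_times_h Sampling times in hours, within the simulated span.
#' @param variables Which of `glucose`, `insulin` to report.
#' @param replicates Replicate devices per condition.
#' @param dose_mM,duration_h Passed to [simulate_gtt()].
#' @return Tibble `condition`, `variable`, `time_h`, `value`, `sd`.
#' @export
generate_gtt_series <- function(device, params, condition = "control",
                                noise = noise_model(cv_or_sd = 0.04),
                                sample_times_h = c(1, 2, 4, 8, 12, 24),
                                variables = c("glucose", "insulin"),
                                replicates = 3, dose_mM = 13,
                                duration_h = 24) {
  stopifnot(inherits(device, "mod_device"), inherits(noise, "noise_model"))
  if (any(sample_times_h < 0 | sample_times_h > duration_h)) {
    abort("sample_times_h outside the simulated span",
          class = "organflux_precondition_error")
  }
  res <- simulate_gtt(device, params, condition, dose_mM = dose_mM,
                      duration_h = duration_h,
                      output_times_h = sample_times_h)
  clean <- bind_rows(
    if ("glucose" %in% variables)
      res$glucose_trajectory %>% mutate(variable = "glucose"),
    if ("insulin" %in% variables)
      res$insulin_trajectory %>% mutate(variable = "insulin")
  ) %>% filter(.data$time_h %in% sample_times_h)
  draws <- with_noise_seed(noise$seed, {
    bind_rows(lapply(seq_len(replicates), function(r) {
      clean %>% mutate(value = apply_noise(.data$value, noise)$values,
                       replicate = r)
    }))
  })
  draws %>%
    group_by(.data$variable, .data$time_h) %>%
    summarise(sd = if (replicates > 1) stats::sd(.data$value) else NA_real_,
              value = mean(.data$value), .groups = "drop") %>%
    mutate(condition = condition) %>%
    select("condition", "variable", "time_h", "value", "sd") %>%
    arrange(.data$variable, .data$time_h)
}
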