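## broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.transport_result <- function(x, ...) x$data

#' @export
glance.transport_result <- function(x, ...) {
  tibble(species = x$species$name, flow_enabled = x$flow_enabled,
         n_times = length(x$time_grid),
         mass_balance_rel_error = x$provenance$mass_balance_rel_error,
         solver = x$provenance$solver)
}

#' @export
autoplot.transport_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_s / 60,
                               y = .data$concentration,
                               colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("%s (%s)", object$species$name,
                              object$species$units),
                  colour = NULL,
                  title = sprintf("%s transport, flow %s",
                                  object$species$name,
                                  if (object$flow_enabled) "on" else "off")) +
    ggplot2::theme_minimal()
}

#' @export
tidy.calibration_report <- function(x, ...) {
  left_join(x$params, x$identifiability, by = "param")
}

#' @export
glance.calibration_report <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged,
         n_params = nrow(x$params),
         n_identifiable = sum(x$identifiability$identifiable))
}

#' @export
tidy.gtt_result <- function(x, ...) x$trajectories

#' @export
glance.gtt_result <- function(x, ...) {
  tibble(condition = x$condition, dose_mM = x$dose_mM,
         peak_insulin = x$peak_insulin, auc_glucose = x$auc_glucose,
         auc_insulin_sustained = x$auc_insulin_sustained)
}

#' @export
autoplot.gtt_result <- function(object, ...) {
  d <- object$trajectories %>% filter(.data$compartment == "CC")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~.data$variable, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(glucose = "CC glucose (mM)",
                            insulin = "CC insulin (µg/L)"))) +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("GTT, %s", object$condition)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.gtt_fit <- function(x, ...) {
  tibble(term = x$free, estimate = unname(x$estimates))
}

#' @export
glance.gtt_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, n_obs = x$n_obs,
         n_free = length(x$free), converged = x$converged)
}

#' Plot flow vs no-flow transport side by side
#'
#' @param result_flow,result_noflow `transport_result`s for the same
#'   species.
#' @return A ggplot.
#' @export
plot_flow_comparison <- function(result_flow, result_noflow) {
  d <- bind_rows(
    result_flow$data %>% mutate(flow = "flow"),
    result_noflow$data %>% mutate(flow = "no flow")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s / 60,
                                  y = .data$concentration,
                                  colour = .data$compartment,
                                  linetype = .data$flow)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("%s (%s)", result_flow$species$name,
                              result_flow$species$units),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
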