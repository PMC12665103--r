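#' Reported transport metrics (device characterisation)
#'
#' The transport read-outs reported for the device characterisation
#' experiments: accumulated percent of the loaded tracer found downstream
#' and flow-to-no-flow concentration folds, for the 4 kDa dextran
#' (insulin-sized), 70 kDa dextran (Fetuin-A-sized) and glucose, at the
#' reported timepoints. These are the calibration/validation observations
#' used by [calibrate_transport_metrics()].
#'
#' @return Tibble with columns `metric`, `species`, `source`, `targets`,
#'   `compartment`, `flow`, `load_conc`, `time_min`, `time_s`, `value`,
#'   `sd`, `units`.
#' @export
#' @examples
#' reported_transport_metrics()
reported_transport_metrics <- function() {
  path <- system.file("extdata", "transport_reported.csv", package = "organflux")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flow = "logical"))
  df$time_s <- convert_units(df$time_min, "min", "s")
  as_tibble(df)
}

#' Reported glucose tolerance test observations
#'
#' The sparse reported GTT read-outs: CC glucose 2 h after a 13 mM injection
#' under the control co-culture, and CC insulin at 1/12/24 h under control
#' and palmitate conditions. Used by [fit_gtt_params()].
#'
#' @return Tibble with columns `condition`, `variable`, `time_h`, `value`,
#'   `sd`.
#' @export
#' @examples
#' reported_gtt_observations()
reported_gtt_observations <- function() {
  path <- system.file("extdata", "gtt_reported.csv", package = "organflux")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
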