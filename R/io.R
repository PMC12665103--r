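## Validated CSV readers/writers for observed-data tables.

timeseries_required <- c("time_s", "compartment", "species",
                         "concentration", "units")

validate_timeseries <- function(x, where = "timeseries") {
  x <- as_tibble(x)
  missing <- setdiff(timeseries_required, names(x))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", where,
                  paste(missing, collapse = ", ")),
          class = "organflux_io_error")
  }
  if (!nrow(x)) return(x)
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  key <- paste(x$time_s, x$compartment, x$species, x$replicate,
               if ("flow" %in% names(x)) x$flow else "")
  if (anyDuplicated(key)) {
    abort(sprintf("%s: duplicated (time, compartment, species, replicate) rows",
                  where),
          class = "organflux_io_error")
  }
  mixed <- x %>% group_by(.data$species) %>%
    summarise(n_units = dplyr::n_distinct(.data$units), .groups = "drop")
  if (any(mixed$n_units > 1)) {
    abort(sprintf("%s: mixed units within species %s", where,
                  paste(mixed$species[mixed$n_units > 1], collapse = ", ")),
          class = "organflux_io_error")
  }
  mono <- x %>%
    group_by(.data$compartment, .data$species, .data$replicate) %>%
    summarise(ok = !is.unsorted(.data$time_s), .groups = "drop")
  if (any(!mono$ok)) {
    abort(sprintf("%s: non-monotone time within a series", where),
          class = "organflux_io_error")
  }
  x
}

#' Read an observed-data time series CSV
#'
#' Schema: `time_s, compartment, species, concentration, units` plus
#' optional `replicate` and `flow`. An empty-but-headered file yields an
#' empty tibble. Duplicate keys, mixed units within a species, and
#' non-monotone time within a series are rejected.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "organflux_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_timeseries(df, where = path)
}

#' Write an observed-data time series CSV
#'
#' `read_timeseries(write_timeseries(x, path))` returns `x`.
#'
#' @param x Time-series tibble (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  x <- validate_timeseries(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a GTT observed-data CSV
#'
#' Schema: `condition, variable, time_h, value, sd` with
#' `variable` in `glucose`/`insulin` (the packaged
#' `gtt_reported.csv` follows it).
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_gtt_observations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "organflux_io_error")
  }
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("condition", "variable", "time_h", "value")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing, collapse = ", ")),
          class = "organflux_io_error")
  }
  bad <- setdiff(unique(df$variable), c("glucose", "insulin"))
  if (length(bad)) {
    abort(sprintf("%s: unknown variable(s) %s", path,
                  paste(bad, collapse = ", ")),
          class = "organflux_io_error")
  }
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  df
}
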