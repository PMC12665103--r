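## JSON device configuration: strict load / write with schema validation.

config_schema <- list(
  top = c("compartments", "convective_edges", "membrane_interfaces",
          "fluid", "shear_fluid", "flow", "channel", "no_flow_path_cm",
          "species", "surrogates"),
  compartments = c("id", "volume_uL", "role"),
  convective_edges = c("from", "to"),
  membrane_interfaces = c("from", "to", "pore_um", "porosity", "kappa_m2",
                          "thickness_um", "area_cm2", "tortuosity"),
  fluid = c("rho_kg_m3", "mu_Pa_s"),
  shear_fluid = c("rho_kg_m3", "mu_Pa_s"),
  flow = c("rate_uL_min", "enabled"),
  channel = c("width_cm", "height_cm", "length_cm"),
  species = c("name", "molecular_weight_kDa", "diffusivity_m2_s",
              "default_units")
)

check_keys <- function(got, allowed, path) {
  unknown <- setdiff(got, allowed)
  if (length(unknown)) {
    abort(sprintf("unknown key(s) at %s: %s", path,
                  paste(unknown, collapse = ", ")),
          class = "organflux_config_error")
  }
  missing <- setdiff(allowed, got)
  if (length(missing)) {
    abort(sprintf("missing key(s) at %s: %s", path,
                  paste(missing, collapse = ", ")),
          class = "organflux_config_error")
  }
}

#' Load a device configuration
#'
#' Reads a JSON device description, validates every field against the schema
#' (unknown keys are rejected with the offending path; all type invariants
#' are checked through the constructors), and returns a ready-to-solve
#' [mod_device()]. The returned device additionally carries the species table
#' (`$species`), the surrogate mapping (`$surrogates`: which tracer stands in
#' for insulin and Fetuin-A) and the fluid used for the wall-shear estimate
#' (`$shear_fluid`; the shear estimate uses the viscosity of
#' aqueous media, ~0.01 poise, not the simulation value).
#'
#' @param path Path to a JSON file such as the packaged `mod_default.json`.
#' @return A [mod_device()] with `species`, `surrogates` and `shear_fluid`.
#' @export
#' @examples
#' dev <- load_config(system.file("extdata", "mod_default.json",
#'                                package = "organflux"))
#' dev$flow$rate_uL_min
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "organflux_config_error")
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(names(cfg), config_schema$top, "top level")
  for (section in c("compartments", "convective_edges",
                    "membrane_interfaces", "species")) {
    check_keys(names(cfg[[section]]), config_schema[[section]],
               paste0("$", section))
  }
  for (section in c("fluid", "shear_fluid", "flow", "channel")) {
    check_keys(names(cfg[[section]]), config_schema[[section]],
               paste0("$", section))
  }
  if (!is.numeric(cfg$no_flow_path_cm) || cfg$no_flow_path_cm <= 0) {
    abort("$no_flow_path_cm: expected a positive length in cm",
          class = "organflux_config_error")
  }
  species <- as_tibble(cfg$species)
  if (any(species$diffusivity_m2_s <= 0)) {
    abort("$species$diffusivity_m2_s: expected positive m^2/s values",
          class = "organflux_config_error")
  }
  surrogates <- as.list(cfg$surrogates)
  miss <- setdiff(unlist(surrogates), species$name)
  if (length(miss)) {
    abort(sprintf("$surrogates: unknown species %s",
                  paste(miss, collapse = ", ")),
          class = "organflux_config_error")
  }
  dev <- mod_device(
    compartments = as_tibble(cfg$compartments),
    convective_edges = as_tibble(cfg$convective_edges),
    membrane_interfaces = as_tibble(cfg$membrane_interfaces),
    fluid = mod_fluid(cfg$fluid$rho_kg_m3, cfg$fluid$mu_Pa_s),
    flow = mod_flow(cfg$flow$rate_uL_min, cfg$flow$enabled),
    channel = mod_channel(cfg$channel$width_cm, cfg$channel$height_cm,
                          cfg$channel$length_cm),
    no_flow_path_cm = cfg$no_flow_path_cm
  )
  dev$shear_fluid <- mod_fluid(cfg$shear_fluid$rho_kg_m3,
                               cfg$shear_fluid$mu_Pa_s)
  dev$species <- species
  dev$surrogates <- surrogates
  dev
}

#' Write a device configuration
#'
#' Inverse of [load_config()]: `load_config(write_config(dev, path))`
#' reproduces the device exactly.
#'
#' @param device A [mod_device()] carrying `species`, `surrogates` and
#'   `shear_fluid` (as returned by [load_config()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(device, path) {
  stopifnot(inherits(device, "mod_device"))
  cfg <- list(
    compartments = device$compartments,
    convective_edges = device$convective_edges,
    membrane_interfaces = device$membrane_interfaces,
    fluid = list(rho_kg_m3 = device$fluid$density_kg_m3,
                 mu_Pa_s = device$fluid$viscosity_Pa_s),
    shear_fluid = list(rho_kg_m3 = device$shear_fluid$density_kg_m3,
                       mu_Pa_s = device$shear_fluid$viscosity_Pa_s),
    flow = list(rate_uL_min = device$flow$rate_uL_min,
                enabled = device$flow$enabled),
    channel = device$channel[c("width_cm", "height_cm", "length_cm")],
    no_flow_path_cm = device$no_flow_path_cm,
    species = device$species,
    surrogates = device$surrogates
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Look up a species definition from a device
#'
#' @param device A [mod_device()] from [load_config()].
#' @param name Species name or a surrogate alias (`"insulin"`, `"feta"`).
#' @return One-row tibble with the species fields.
#' @export
device_species <- function(device, name) {
  if (!is.null(device$surrogates[[name]])) name <- device$surrogates[[name]]
  row <- device$species[device$species$name == name, ]
  if (!nrow(row)) {
    abort(sprintf("unknown species '%s'", name),
          class = "organflux_species_error")
  }
  row
}
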