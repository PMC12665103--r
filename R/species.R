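#' Define a transported species
#'
#' @param name Species label.
#' @param diffusivity_m2_s Free-solution diffusion coefficient in m^2/s.
#' @param initial_loading Named numeric vector mapping compartment id to
#'   initial concentration (mM for glucose, ug/mL for dextrans); compartments
#'   not named start at 0.
#' @param molecular_weight_kDa Molecular weight in kDa (annotation only).
#' @param units Concentration units label carried through results.
#' @return An object of class `mod_species`.
#' @export
#' @examples
#' mod_species("dextran4", 1.35e-10, c(POC = 1), 4, "ug/mL")
mod_species <- function(name, diffusivity_m2_s, initial_loading,
                        molecular_weight_kDa = NA_real_, units = "ug/mL") {
  if (diffusivity_m2_s <= 0) {
    abort("diffusivity must be > 0", class = "organflux_species_error")
  }
  initial_loading <- unlist(initial_loading)
  if (length(initial_loading) && (is.null(names(initial_loading)) ||
                                  any(!nzchar(names(initial_loading))))) {
    abort("initial_loading must be a named vector (compartment -> concentration)",
          class = "organflux_species_error")
  }
  if (any(initial_loading < 0)) {
    abort("initial loadings must be >= 0", class = "organflux_species_error")
  }
  structure(list(name = name, diffusivity_m2_s = diffusivity_m2_s,
                 initial_loading = initial_loading,
                 molecular_weight_kDa = molecular_weight_kDa, units = units),
            class = "mod_species")
}

#' Build a tracer species from a device's species table
#'
#' Convenience wrapper: looks the species (or surrogate alias) up in the
#' device configuration and loads a single compartment, following the
#' simulation defaults (1 ug/mL dextran tracers, 13 mM glucose).
#'
#' @param device A [mod_device()] from [load_config()].
#' @param name Species name or surrogate alias.
#' @param loaded_compartment Compartment id(s) receiving the initial load.
#' @param concentration Initial concentration in the species' default units.
#' @return A [mod_species()].
#' @export
#' @examples
#' dev <- mod_device_default()
#' tracer_species(dev, "dextran4", "POC", 1)
tracer_species <- function(device, name, loaded_compartment, concentration) {
  row <- device_species(device, name)
  mod_species(row$name, row$diffusivity_m2_s,
              setNames(rep(concentration, length.out = length(loaded_compartment)),
                       loaded_compartment),
              row$molecular_weight_kDa, row$default_units)
}
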