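#' Unit conversion factors
#'
#' The package computes internally in a coherent cm-g-s system: lengths in
#' cm, areas in cm^2, volumes in cm^3, times in s, diffusivities in cm^2/s,
#' conductances and volumetric flows in cm^3/s, dynamic viscosity in g/(cm s)
#' (poise), pressure in dyne/cm^2, and stress in dyne/cm^2. User-facing
#' interfaces accept the field's customary units (uL, uL/min, um, m^2/s,
#' Pa, Pa s, kg/m^3) and convert them here. This table is the only place
#' unit factors appear.
#'
#' @return A tibble with columns `from`, `to`, `factor` (multiply a value in
#'   `from` by `factor` to obtain `to`).
#' @export
#' @examples
#' unit_conversion_table()
unit_conversion_table <- function() {
  tibble::tribble(
    ~from,       ~to,        ~factor,
    "uL",        "cm3",      1e-3,
    "mL",        "cm3",      1,
    "uL/min",    "cm3/s",    1e-3 / 60,
    "um",        "cm",       1e-4,
    "mm",        "cm",       1e-1,
    "m",         "cm",       1e2,
    "m2",        "cm2",      1e4,
    "m2/s",      "cm2/s",    1e4,
    "Pa",        "dyne/cm2", 10,
    "Pa.s",      "poise",    10,
    "kg/m3",     "g/cm3",    1e-3,
    "min",       "s",        60,
    "h",         "s",        3600,
    "cm/s",      "cm/s",     1
  )
}

#' Convert a value between units
#'
#' @param x Numeric vector.
#' @param from,to Unit labels present in [unit_conversion_table()]. Either a
#'   direct `from -> to` row or its inverse must exist.
#' @return `x` expressed in `to`.
#' @export
#' @examples
#' convert_units(600, "uL/min", "cm3/s") # 0.01
convert_units <- function(x, from, to) {
  if (identical(from, to)) return(x)
  tab <- unit_conversion_table()
  hit <- tab$from == from & tab$to == to
  if (any(hit)) return(x * tab$factor[hit][1])
  inv <- tab$from == to & tab$to == from
  if (any(inv)) return(x / tab$factor[inv][1])
  abort(sprintf("no conversion from '%s' to '%s'", from, to),
        class = "organflux_unit_error")
}
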