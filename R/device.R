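#' Rectangular channel geometry
#'
#' @param width_cm,height_cm Cross-section of the connecting channel in cm.
#' @param length_cm Axial length of the channel in cm; also sets the channel
#'   volume of the default device.
#' @return An object of class `mod_channel`.
#' @export
#' @examples
#' mod_channel(0.7, 0.3, 1.0)
mod_channel <- function(width_cm, height_cm, length_cm = 1.0) {
  stopifnot(is.numeric(width_cm), is.numeric(height_cm), is.numeric(length_cm))
  if (width_cm <= 0 || height_cm <= 0 || length_cm <= 0) {
    abort("channel dimensions must be strictly positive",
          class = "organflux_geometry_error")
  }
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 length_cm = length_cm), class = "mod_channel")
}

#' Culture-medium fluid properties
#'
#' @param density_kg_m3 Density in kg/m^3.
#' @param viscosity_Pa_s Dynamic viscosity in Pa s.
#' @return An object of class `mod_fluid`.
#' @export
#' @examples
#' mod_fluid(1030, 0.0025)
mod_fluid <- function(density_kg_m3 = 1030, viscosity_Pa_s = 0.0025) {
  if (density_kg_m3 <= 0 || viscosity_Pa_s <= 0) {
    abort("fluid density and viscosity must be strictly positive",
          class = "organflux_fluid_error")
  }
  structure(list(density_kg_m3 = density_kg_m3,
                 viscosity_Pa_s = viscosity_Pa_s), class = "mod_fluid")
}

#' Porous membrane properties
#'
#' @param pore_um Pore size in um.
#' @param porosity Open fraction, in (0, 1].
#' @param kappa_m2 Darcy permeability in m^2.
#' @param thickness_um Membrane thickness in um.
#' @param area_cm2 Exchange area in cm^2.
#' @param tortuosity Dimensionless path-length correction, >= 1.
#' @return An object of class `mod_membrane`.
#' @export
#' @examples
#' mod_membrane(1.0, 0.8, 2.5e-14, 50, 0.2)
mod_membrane <- function(pore_um = 1.0, porosity = 0.8, kappa_m2 = 2.5e-14,
                         thickness_um = 50, area_cm2 = 0.2, tortuosity = 1) {
  if (porosity <= 0 || porosity > 1) {
    abort("porosity must be in (0, 1]", class = "organflux_membrane_error")
  }
  if (any(c(pore_um, kappa_m2, thickness_um, area_cm2) <= 0)) {
    abort("membrane lengths, areas and permeability must be strictly positive",
          class = "organflux_membrane_error")
  }
  if (tortuosity < 1) {
    abort("tortuosity must be >= 1", class = "organflux_membrane_error")
  }
  structure(list(pore_um = pore_um, porosity = porosity, kappa_m2 = kappa_m2,
                 thickness_um = thickness_um, area_cm2 = area_cm2,
                 tortuosity = tortuosity), class = "mod_membrane")
}

#' Recirculating flow configuration
#'
#' @param rate_uL_min Volumetric rate in uL/min; must be >= 0.
#' @param enabled Logical; `FALSE` forces an effective rate of 0.
#' @return An object of class `mod_flow`.
#' @export
mod_flow <- function(rate_uL_min = 600, enabled = TRUE) {
  if (rate_uL_min < 0) {
    abort("flow rate must be >= 0", class = "organflux_flow_error")
  }
  structure(list(rate_uL_min = rate_uL_min, enabled = isTRUE(enabled)),
            class = "mod_flow")
}

effective_rate_cm3_s <- function(flow) {
  if (!flow$enabled) return(0)
  convert_units(flow$rate_uL_min, "uL/min", "cm3/s")
}

#' Build a multi-organoid device model
#'
#' A device is a set of well-mixed compartments joined by directed convective
#' edges (the recirculating loop) and by membrane interfaces (diffusive
#' exchange across the porous PTFE membrane). The no-flow diffusive path
#' through the stagnant channel is characterised by an effective path length;
#' see [simulate_transport()].
#'
#' @param compartments Tibble with columns `id`, `volume_uL`, `role`
#'   (`"organoid-chamber"`, `"channel"` or `"tubing"`).
#' @param convective_edges Tibble with columns `from`, `to`; when flow is
#'   enabled the edges must form a closed loop (every compartment touched has
#'   exactly one inflow and one outflow).
#' @param membrane_interfaces Tibble with columns `from`, `to` plus the
#'   [mod_membrane()] fields (`pore_um`, `porosity`, `kappa_m2`,
#'   `thickness_um`, `area_cm2`, `tortuosity`).
#' @param fluid A [mod_fluid()].
#' @param flow A [mod_flow()].
#' @param channel A [mod_channel()]; its cross-section `w*h` is the area of
#'   the no-flow diffusive path.
#' @param no_flow_path_cm Effective diffusion path length (cm) placed in
#'   series with each membrane interface when flow is off. A lumped stand-in
#'   for the stagnant layer in the unstirred channel; calibrated by
#'   [calibrate_geometry()].
#' @return An object of class `mod_device`.
#' @export
#' @examples
#' dev <- mod_device_default()
#' dev$compartments
mod_device <- function(compartments, convective_edges, membrane_interfaces,
                       fluid = mod_fluid(), flow = mod_flow(),
                       channel = mod_channel(0.7, 0.3, 1.0),
                       no_flow_path_cm = 0.05) {
  compartments <- as_tibble(compartments)
  convective_edges <- as_tibble(convective_edges)
  membrane_interfaces <- as_tibble(membrane_interfaces)
  req <- c("id", "volume_uL", "role")
  if (!all(req %in% names(compartments))) {
    abort("compartments need columns id, volume_uL, role",
          class = "organflux_device_error")
  }
  if (anyDuplicated(compartments$id)) {
    abort("compartment ids must be unique", class = "organflux_device_error")
  }
  if (any(compartments$volume_uL <= 0)) {
    abort("compartment volumes must be strictly positive",
          class = "organflux_device_error")
  }
  bad_role <- setdiff(compartments$role,
                      c("organoid-chamber", "channel", "tubing"))
  if (length(bad_role)) {
    abort(sprintf("unknown compartment role: %s",
                  paste(bad_role, collapse = ", ")),
          class = "organflux_device_error")
  }
  ids <- compartments$id
  for (tbl in list(convective_edges, membrane_interfaces)) {
    miss <- setdiff(c(tbl$from, tbl$to), ids)
    if (length(miss)) {
      abort(sprintf("edge references unknown compartment: %s",
                    paste(miss, collapse = ", ")),
            class = "organflux_device_error")
    }
  }
  if (flow$enabled && nrow(convective_edges)) {
    touched <- union(convective_edges$from, convective_edges$to)
    n_out <- table(factor(convective_edges$from, levels = touched))
    n_in <- table(factor(convective_edges$to, levels = touched))
    if (!all(n_out == 1) || !all(n_in == 1)) {
      abort("convective edges must form a closed loop (one inflow and one outflow per compartment)",
            class = "organflux_device_error")
    }
  }
  mreq <- c("from", "to", "pore_um", "porosity", "kappa_m2", "thickness_um",
            "area_cm2", "tortuosity")
  if (nrow(membrane_interfaces) && !all(mreq %in% names(membrane_interfaces))) {
    abort(sprintf("membrane_interfaces need columns: %s",
                  paste(mreq, collapse = ", ")),
          class = "organflux_device_error")
  }
  if (nrow(membrane_interfaces)) {
    # run each row through the constructor so invariants are enforced
    purrr::pwalk(membrane_interfaces[setdiff(mreq, c("from", "to"))],
                 mod_membrane)
  }
  structure(list(compartments = compartments,
                 convective_edges = convective_edges,
                 membrane_interfaces = membrane_interfaces,
                 fluid = fluid, flow = flow, channel = channel,
                 no_flow_path_cm = no_flow_path_cm),
            class = "mod_device")
}

#' @export
print.mod_device <- function(x, ...) {
  cat("<mod_device> ", nrow(x$compartments), " compartments, ",
      nrow(x$convective_edges), " convective edges, ",
      nrow(x$membrane_interfaces), " membrane interfaces\n", sep = "")
  cat("flow:", if (x$flow$enabled) sprintf("%g uL/min", x$flow$rate_uL_min)
      else "off", "\n")
  print(x$compartments)
  invisible(x)
}

#' The default device
#'
#' The packaged configuration: POC and LOC organoid chambers (300 uL each)
#' above a 1.0 um-pore PTFE membrane (porosity 0.8, Darcy permeability
#' 2.5e-14 m^2), a 0.7 x 0.3 cm connecting channel (CC, 210 uL) perfused at
#' 600 uL/min, and a LOOP tubing compartment (390 uL) closing the
#' recirculating 600 uL circuit.
#'
#' @param flow_enabled Logical, convective flow on or off.
#' @return A [mod_device()].
#' @export
mod_device_default <- function(flow_enabled = TRUE) {
  path <- system.file("extdata", "mod_default.json", package = "organflux")
  dev <- load_config(path)
  dev$flow$enabled <- isTRUE(flow_enabled)
  dev
}

total_volume_uL <- function(device) sum(device$compartments$volume_uL)

#' Wall shear stress in a rectangular channel
#'
#' tau = 6 mu Q / (w h^2), the thin-channel estimate of the shear stress a
#' pressure-driven flow exerts on the channel wall. Inputs are converted to
#' CGS so the result is in dyne/cm^2.
#'
#' @param flow A [mod_flow()] (Q taken as 0 when disabled).
#' @param channel A [mod_channel()] providing w and h in cm.
#' @param fluid A [mod_fluid()]; viscosity converted from Pa s to poise.
#' @return Shear stress in dyne/cm^2.
#' @export
#' @examples
#' # the default device: 600 uL/min in a 0.7 x 0.3 cm channel, mu ~ 0.01 P
#' wall_shear_stress(mod_flow(600), mod_channel(0.7, 0.3),
#'                   mod_fluid(1000, 0.001))
wall_shear_stress <- function(flow, channel, fluid) {
  stopifnot(inherits(flow, "mod_flow"), inherits(channel, "mod_channel"),
            inherits(fluid, "mod_fluid"))
  q_cgs <- effective_rate_cm3_s(flow)
  mu_cgs <- convert_units(fluid$viscosity_Pa_s, "Pa.s", "poise")
  6 * mu_cgs * q_cgs / (channel$width_cm * channel$height_cm^2)
}

#' Circulation time of the recirculating loop
#'
#' @param total_volume_uL Total circulating media volume in uL.
#' @param flow A [mod_flow()]; must be enabled with rate > 0.
#' @return Time to circulate the full volume once, in minutes.
#' @export
#' @examples
#' circulation_time(600, mod_flow(600)) # 1 minute
circulation_time <- function(total_volume_uL, flow) {
  stopifnot(inherits(flow, "mod_flow"))
  if (!flow$enabled || flow$rate_uL_min == 0) {
    abort("circulation time is undefined without flow",
          class = "organflux_undefined_circulation")
  }
  total_volume_uL / flow$rate_uL_min
}

#' Darcy (superficial) velocity through the membrane
#'
#' v = (kappa / mu) * (dP / L). Used as a diagnostic of pressure-driven
#' transmembrane flow; the transport model is diffusion-dominated by default.
#'
#' @param membrane A [mod_membrane()].
#' @param fluid A [mod_fluid()].
#' @param pressure_drop_Pa Transmembrane pressure difference in Pa; the sign
#'   of the result follows the sign of the drop.
#' @return Superficial velocity in m/s.
#' @export
#' @examples
#' darcy_velocity(mod_membrane(kappa_m2 = 2.5e-14, thickness_um = 100),
#'                mod_fluid(1030, 0.0025), 10) # 1e-6 m/s
darcy_velocity <- function(membrane, fluid, pressure_drop_Pa) {
  stopifnot(inherits(membrane, "mod_membrane"), inherits(fluid, "mod_fluid"))
  thickness_m <- membrane$thickness_um * 1e-6
  (membrane$kappa_m2 / fluid$viscosity_Pa_s) *
    (pressure_drop_Pa / thickness_m)
}

#' Effective diffusive conductance of a membrane interface
#'
#' G = D * porosity * A / (thickness * tortuosity), the lumped volumetric
#' exchange coefficient that reduces membrane transport to a single
#' first-order term G * (C_j - C_i).
#'
#' @param membrane A [mod_membrane()].
#' @param diffusivity_m2_s Species free-solution diffusivity in m^2/s.
#' @return Conductance in cm^3/s.
#' @export
#' @examples
#' membrane_conductance(mod_membrane(area_cm2 = 1), 9.58e-10)
membrane_conductance <- function(membrane, diffusivity_m2_s) {
  stopifnot(inherits(membrane, "mod_membrane"))
  if (diffusivity_m2_s <= 0) {
    abort("diffusivity must be > 0", class = "organflux_species_error")
  }
  d_cm2_s <- convert_units(diffusivity_m2_s, "m2/s", "cm2/s")
  thick_cm <- convert_units(membrane$thickness_um, "um", "cm")
  d_cm2_s * membrane$porosity * membrane$area_cm2 /
    (thick_cm * membrane$tortuosity)
}
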