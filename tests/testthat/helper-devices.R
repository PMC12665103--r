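# Small devices and independent oracles used across the suite.

empty_edges <- function() {
  tibble::tibble(from = character(), to = character())
}

membrane_row <- function(from, to, area_cm2, thickness_um = 50,
                         porosity = 0.8, tortuosity = 1) {
  tibble::tibble(from = from, to = to, pore_um = 1, porosity = porosity,
                 kappa_m2 = 2.5e-14, thickness_um = thickness_um,
                 area_cm2 = area_cm2, tortuosity = tortuosity)
}

# Closed pair of well-mixed compartments joined by one membrane edge.
# Flow is "enabled" at rate 0 so the no-flow series path stays out of the
# conductance (the membrane is the only exchange route).
two_comp_device <- function(v1_uL = 300, v2_uL = 300, area_cm2 = 0.5,
                            porosity = 0.8, thickness_um = 50) {
  mod_device(
    compartments = tibble::tibble(id = c("A", "B"),
                                  volume_uL = c(v1_uL, v2_uL),
                                  role = c("organoid-chamber", "channel")),
    convective_edges = empty_edges(),
    membrane_interfaces = membrane_row("A", "B", area_cm2,
                                       thickness_um = thickness_um,
                                       porosity = porosity),
    flow = mod_flow(0, enabled = TRUE)
  )
}

# Three compartments in a chain A-B-C, membrane edges only.
three_comp_device <- function(v_uL = c(300, 200, 400),
                              areas_cm2 = c(0.4, 0.15)) {
  mod_device(
    compartments = tibble::tibble(id = c("A", "B", "C"), volume_uL = v_uL,
                                  role = c("organoid-chamber", "channel",
                                           "organoid-chamber")),
    convective_edges = empty_edges(),
    membrane_interfaces = dplyr::bind_rows(
      membrane_row("A", "B", areas_cm2[1]),
      membrane_row("B", "C", areas_cm2[2])),
    flow = mod_flow(0, enabled = TRUE)
  )
}

# Independent closed-form solution for the two-compartment exchange
# C1(t) = Ceq + (C1(0) - Ceq) exp(-k t), k = G (1/V1 + 1/V2).
two_comp_closed_form <- function(c1_0, c2_0, v1_cm3, v2_cm3, g_cm3_s, t_s) {
  ceq <- (c1_0 * v1_cm3 + c2_0 * v2_cm3) / (v1_cm3 + v2_cm3)
  k <- g_cm3_s * (1 / v1_cm3 + 1 / v2_cm3)
  list(c1 = ceq + (c1_0 - ceq) * exp(-k * t_s),
       c2 = ceq + (c2_0 - ceq) * exp(-k * t_s))
}

# Hand unit-conversion oracle for the membrane conductance (computed
# independently of the package's conversion table): D [m^2/s] -> cm^2/s via
# 1 m^2 = 1e4 cm^2; thickness [um] -> cm via 1 um = 1e-4 cm.
conductance_oracle_cm3_s <- function(d_m2_s, porosity, area_cm2,
                                     thickness_um, tortuosity = 1) {
  (d_m2_s * 1e4) * porosity * area_cm2 /
    ((thickness_um * 1e-4) * tortuosity)
}

# Independent matrix-exponential oracle: builds the exchange-rate matrix
# straight from the device tables (membrane conductances + convective loop)
# and propagates with Matrix::expm.
expm_oracle <- function(device, d_m2_s, flow_enabled, y0, times) {
  comp <- device$compartments
  v <- stats::setNames(comp$volume_uL * 1e-3, comp$id)
  n <- length(v)
  a <- matrix(0, n, n, dimnames = list(comp$id, comp$id))
  mi <- device$membrane_interfaces
  for (k in seq_len(nrow(mi))) {
    g <- conductance_oracle_cm3_s(d_m2_s, mi$porosity[k], mi$area_cm2[k],
                                  mi$thickness_um[k], mi$tortuosity[k])
    if (!flow_enabled) {
      g_path <- (d_m2_s * 1e4) *
        (device$channel$width_cm * device$channel$height_cm) /
        device$no_flow_path_cm
      g <- 1 / (1 / g + 1 / g_path)
    }
    i <- mi$from[k]; j <- mi$to[k]
    a[i, i] <- a[i, i] - g / v[i]; a[i, j] <- a[i, j] + g / v[i]
    a[j, j] <- a[j, j] - g / v[j]; a[j, i] <- a[j, i] + g / v[j]
  }
  if (flow_enabled && device$flow$enabled) {
    q <- device$flow$rate_uL_min * 1e-3 / 60
    ce <- device$convective_edges
    for (k in seq_len(nrow(ce))) {
      s <- ce$from[k]; t <- ce$to[k]
      a[t, s] <- a[t, s] + q / v[t]
      a[s, s] <- a[s, s] - q / v[s]
    }
  }
  t(vapply(times, function(t_s) {
    as.numeric(Matrix::expm(a * t_s) %*% y0)
  }, numeric(n)))
}

calibrated_default_device <- function() {
  dev <- mod_device_default()
  reported <- reported_transport_metrics()
  rep <- calibrate_transport_metrics(
    dev, dplyr::filter(reported, species == "dextran4"),
    free_params = c("exchange_area_POC", "exchange_area_LOC",
                    "channel_path_length"))
  rep$device
}
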