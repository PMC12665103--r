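## Compartmental advection-diffusion transport over the device network.

# Linear exchange-rate matrix in concentration form: dC/dt = A %*% C.
# Membrane interfaces contribute G*(C_j - C_i)/V_i with
# G = D*eps*A/(L*tau); with flow off, G is placed in series with the
# unstirred channel-path conductance D*(w*h)/L_path and convection is zero.
transport_matrix <- function(device, diffusivity_m2_s, flow_enabled) {
  comp <- device$compartments
  v <- setNames(convert_units(comp$volume_uL, "uL", "cm3"), comp$id)
  n <- length(v)
  a <- matrix(0, n, n, dimnames = list(comp$id, comp$id))
  add_exchange <- function(a, i, j, g) {
    a[i, i] <- a[i, i] - g / v[i]; a[i, j] <- a[i, j] + g / v[i]
    a[j, j] <- a[j, j] - g / v[j]; a[j, i] <- a[j, i] + g / v[j]
    a
  }
  d_cm2_s <- convert_units(diffusivity_m2_s, "m2/s", "cm2/s")
  mi <- device$membrane_interfaces
  if (nrow(mi)) {
    for (k in seq_len(nrow(mi))) {
      mem <- mod_membrane(mi$pore_um[k], mi$porosity[k], mi$kappa_m2[k],
                          mi$thickness_um[k], mi$area_cm2[k], mi$tortuosity[k])
      g <- membrane_conductance(mem, diffusivity_m2_s)
      if (!flow_enabled) {
        a_cc <- device$channel$width_cm * device$channel$height_cm
        g_path <- d_cm2_s * a_cc / device$no_flow_path_cm
        g <- 1 / (1 / g + 1 / g_path)
      }
      a <- add_exchange(a, mi$from[k], mi$to[k], g)
    }
  }
  if (flow_enabled) {
    q <- effective_rate_cm3_s(device$flow)
    ce <- device$convective_edges
    if (q > 0 && nrow(ce)) {
      for (k in seq_len(nrow(ce))) {
        s <- ce$from[k]; t <- ce$to[k]
        a[t, s] <- a[t, s] + q / v[t]
        a[s, s] <- a[s, s] - q / v[s]
      }
    }
  }
  list(a = a, volumes_cm3 = v)
}

#' Simulate species transport through the device
#'
#' Integrates the well-mixed compartment network
#' \deqn{dC_i/dt = [\sum Q (C_{up} - C_i) + \sum G (C_j - C_i)] / V_i}
#' with a stiff-capable integrator (lsoda, relative tolerance 1e-8, absolute
#' tolerance 1e-12). With flow off, all convective terms vanish and each
#' membrane conductance acts in series with the diffusive conductance of the
#' stagnant channel path, `D * w * h / no_flow_path_cm`.
#'
#' @param device A [mod_device()].
#' @param species A [mod_species()] (or a name resolvable by
#'   [tracer_species()] when `loaded_compartment`/`concentration` are given).
#' @param flow_enabled Logical; overrides `device$flow$enabled` if not `NULL`.
#' @param duration_s Total simulated time in seconds.
#' @param output_times Times (s) at which concentrations are reported; must
#'   lie within `[0, duration_s]`. Defaults to 200 evenly spaced times.
#' @return A `transport_result`: list with `data` (tibble `time_s`,
#'   `compartment`, `species`, `concentration`, `units`), `volumes_cm3`, and
#'   `provenance` (solver settings, parameter snapshot, mass-balance error).
#' @export
#' @examples
#' dev <- mod_device_default()
#' tr <- simulate_transport(dev, tracer_species(dev, "dextran4", "POC", 1),
#'                          duration_s = 3600)
#' head(tidy(tr))
simulate_transport <- function(device, species, flow_enabled = NULL,
                               duration_s, output_times = NULL) {
  stopifnot(inherits(device, "mod_device"), inherits(species, "mod_species"))
  if (duration_s <= 0) {
    abort("duration must be > 0", class = "organflux_precondition_error")
  }
  if (is.null(flow_enabled)) flow_enabled <- device$flow$enabled
  if (is.null(output_times)) {
    output_times <- seq(0, duration_s, length.out = 200)
  }
  if (any(output_times < 0 | output_times > duration_s)) {
    abort("output_times must lie within [0, duration]",
          class = "organflux_precondition_error")
  }
  output_times <- sort(unique(c(0, output_times)))
  mats <- transport_matrix(device, species$diffusivity_m2_s, flow_enabled)
  ids <- device$compartments$id
  y0 <- setNames(numeric(length(ids)), ids)
  extra <- setdiff(names(species$initial_loading), ids)
  if (length(extra)) {
    abort(sprintf("initial loading names unknown compartment: %s",
                  paste(extra, collapse = ", ")),
          class = "organflux_precondition_error")
  }
  y0[names(species$initial_loading)] <- species$initial_loading
  rtol <- 1e-8; atol <- 1e-12
  a <- mats$a
  sol <- deSolve::ode(
    y = y0, times = output_times,
    func = function(t, y, p) list(as.vector(a %*% y)),
    jacfunc = function(t, y, p) a, jactype = "fullusr",
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(output_times)) {
    abort("stiff solver failed before reaching the requested duration",
          class = "organflux_solver_error")
  }
  conc <- sol[, ids, drop = FALSE]
  # round-off guard: tiny negativity is clipped, larger negativity is a bug
  neg_tol <- 100 * atol
  if (any(conc < -neg_tol)) {
    abort(sprintf("negative concentration beyond tolerance (min %.3e)",
                  min(conc)),
          class = "organflux_integrity_error")
  }
  conc[conc < 0] <- 0
  mass <- conc %*% mats$volumes_cm3[ids]
  mass_err <- if (mass[1] > 0) max(abs(mass - mass[1])) / mass[1] else 0
  sp_name <- species$name
  sp_units <- species$units
  data <- as_tibble(as.data.frame(sol[, c("time", ids)])) %>%
    rename(time_s = "time") %>%
    tidyr::pivot_longer(all_of(ids), names_to = "compartment",
                        values_to = "concentration") %>%
    mutate(species = sp_name, units = sp_units) %>%
    select("time_s", "compartment", "species", "concentration", "units")
  structure(list(
    data = data,
    time_grid = output_times,
    volumes_cm3 = mats$volumes_cm3,
    species = species,
    flow_enabled = flow_enabled,
    provenance = list(
      solver = "lsoda", rtol = rtol, atol = atol,
      flow_enabled = flow_enabled,
      flow_rate_uL_min = device$flow$rate_uL_min,
      no_flow_path_cm = device$no_flow_path_cm,
      membrane_areas_cm2 = device$membrane_interfaces$area_cm2,
      membrane_thickness_um = device$membrane_interfaces$thickness_um,
      diffusivity_m2_s = species$diffusivity_m2_s,
      mass_balance_rel_error = mass_err,
      package_version = as.character(utils::packageVersion("organflux"))
    )
  ), class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result> species:", x$species$name,
      if (x$flow_enabled) "(flow)" else "(no flow)",
      sprintf("| %d times x %d compartments\n", length(x$time_grid),
              length(x$volumes_cm3)))
  cat(sprintf("mass balance rel. error: %.2e\n",
              x$provenance$mass_balance_rel_error))
  invisible(x)
}

result_concentration <- function(result, compartment, t) {
  d <- result$data
  i <- d$compartment == compartment & abs(d$time_s - t) < 1e-9
  if (!any(i)) {
    abort(sprintf("time %g s is not on the output grid for %s", t, compartment),
          class = "organflux_precondition_error")
  }
  d$concentration[i][1]
}

#' Percent of initial source mass found in target compartments
#'
#' @param result A `transport_result`.
#' @param source Compartment that carried the initial load.
#' @param target Compartment id(s) whose mass is summed.
#' @param t Time in seconds; must be on the output grid.
#' @return Percentage, `100 * mass(target, t) / mass(source, 0)`.
#' @export
#' @examples
#' dev <- mod_device_default()
#' tr <- simulate_transport(dev, tracer_species(dev, "dextran4", "POC", 1),
#'                          duration_s = 10800, output_times = c(0, 10800))
#' percent_transferred(tr, "POC", c("CC", "LOC", "LOOP"), 10800)
percent_transferred <- function(result, source, target, t) {
  stopifnot(inherits(result, "transport_result"))
  v <- result$volumes_cm3
  c0 <- result_concentration(result, source, 0)
  m0 <- c0 * v[source]
  if (m0 <= 0) {
    abort("source compartment had zero initial mass",
          class = "organflux_undefined_metric")
  }
  m_t <- sum(vapply(target, function(k) {
    result_concentration(result, k, t) * v[[k]]
  }, numeric(1)))
  unname(100 * m_t / m0)
}

#' Flow-to-no-flow concentration ratio
#'
#' @param result_flow,result_noflow `transport_result`s for the same species
#'   and device, with and without flow; grids must match.
#' @param compartment Compartment id where concentrations are compared.
#' @param species Species name (consistency check).
#' @param t Time in seconds, on the shared grid.
#' @return Dimensionless ratio `C_flow / C_noflow`.
#' @export
fold_enhancement <- function(result_flow, result_noflow, compartment,
                             species, t) {
  stopifnot(inherits(result_flow, "transport_result"),
            inherits(result_noflow, "transport_result"))
  if (!identical(result_flow$species$name, species) ||
      !identical(result_noflow$species$name, species)) {
    abort("results are not for the requested species",
          class = "organflux_precondition_error")
  }
  if (!isTRUE(all.equal(result_flow$time_grid, result_noflow$time_grid))) {
    abort("results do not share a time grid",
          class = "organflux_precondition_error")
  }
  c_f <- result_concentration(result_flow, compartment, t)
  c_n <- result_concentration(result_noflow, compartment, t)
  if (c_n == 0) {
    abort("no-flow concentration is zero: fold enhancement overflows",
          class = "organflux_overflow")
  }
  c_f / c_n
}
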