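test_that("a closed two-compartment pair matches the analytic exponential", {
  dev <- two_comp_device(v1_uL = 300, v2_uL = 450, area_cm2 = 0.5)
  d <- 1.35e-10
  g <- membrane_conductance(mod_membrane(porosity = 0.8, thickness_um = 50,
                                         area_cm2 = 0.5), d)
  times <- c(0, 600, 1800, 3600, 7200, 10800)
  tr <- simulate_transport(dev, mod_species("tracer", d, c(A = 1)),
                           duration_s = max(times), output_times = times)
  for (t in times) {
    exact <- two_comp_closed_form(1, 0, 0.3, 0.45, g, t)
    expect_equal(result_concentration <- tidy(tr) %>%
                   dplyr::filter(compartment == "A", time_s == t) %>%
                   dplyr::pull(concentration),
                 exact$c1, tolerance = 1e-6)
    expect_equal(tidy(tr) %>%
                   dplyr::filter(compartment == "B", time_s == t) %>%
                   dplyr::pull(concentration),
                 exact$c2, tolerance = 1e-6)
  }
})

test_that("zero loading gives identically zero trajectories", {
  dev <- two_comp_device()
  tr <- simulate_transport(dev, mod_species("tracer", 1e-10, c(A = 0)),
                           duration_s = 3600)
  expect_true(all(tidy(tr)$concentration == 0))
})

test_that("closed connected devices equilibrate to mass over volume", {
  dev <- mod_device_default()
  sp <- tracer_species(dev, "glucose", "CC", 13)
  # a week of simulated time: far beyond every exchange timescale
  tr <- simulate_transport(dev, sp, duration_s = 6.048e5,
                           output_times = c(0, 6.048e5))
  v <- tr$volumes_cm3
  c_eq <- 13 * v[["CC"]] / sum(v)
  final <- tidy(tr) %>% dplyr::filter(time_s == 6.048e5)
  expect_equal(final$concentration, rep(c_eq, 4), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("mass is conserved to 1e-6 on randomized closed devices", {
  set.seed(31)
  for (i in 1:8) {
    dev <- three_comp_device(v_uL = runif(3, 50, 600),
                             areas_cm2 = runif(2, 0.05, 1))
    d <- 10^runif(1, -11, -9.02)
    load <- sample(c("A", "B", "C"), 1)
    tr <- simulate_transport(dev, mod_species("x", d, setNames(runif(1, 0.5, 13), load)),
                             duration_s = 86400,
                             output_times = seq(0, 86400, length.out = 25))
    expect_lt(tr$provenance$mass_balance_rel_error, 1e-6)
  }
  # and for the full recirculating device under flow and no flow
  dev <- mod_device_default()
  for (fl in c(TRUE, FALSE)) {
    tr <- simulate_transport(dev, tracer_species(dev, "dextran4", "POC", 1),
                             flow_enabled = fl, duration_s = 10800)
    expect_lt(tr$provenance$mass_balance_rel_error, 1e-6)
  }
})

test_that("solver agrees with the matrix-exponential oracle on small systems", {
  set.seed(41)
  times <- c(0, 900, 3600, 14400)
  for (i in 1:6) {
    dev <- three_comp_device(v_uL = runif(3, 100, 500),
                             areas_cm2 = runif(2, 0.05, 0.8))
    d <- 10^runif(1, -11, -9.02)
    y0 <- c(A = 1, B = 0, C = runif(1, 0, 0.5))
    tr <- simulate_transport(dev, mod_species("x", d, y0[y0 > 0]),
                             duration_s = max(times), output_times = times)
    oracle <- expm_oracle(dev, d, flow_enabled = TRUE, y0 = y0, times = times)
    got <- tidy(tr) %>%
      tidyr::pivot_wider(names_from = compartment,
                         values_from = concentration) %>%
      dplyr::arrange(time_s)
    expect_equal(as.matrix(got[, c("A", "B", "C")]),
                 oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # two-compartment pair with the no-flow series path engaged
  dev2 <- two_comp_device()
  dev2$flow <- mod_flow(0, enabled = FALSE)
  tr2 <- simulate_transport(dev2, mod_species("x", 1.35e-10, c(A = 1)),
                            flow_enabled = FALSE,
                            duration_s = max(times), output_times = times)
  oracle2 <- expm_oracle(dev2, 1.35e-10, flow_enabled = FALSE,
                         y0 = c(A = 1, B = 0), times = times)
  got2 <- tidy(tr2) %>%
    tidyr::pivot_wider(names_from = compartment, values_from = concentration) %>%
    dplyr::arrange(time_s)
  expect_equal(as.matrix(got2[, c("A", "B")]), oracle2, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("percent_transferred behaves at its boundary cases", {
  dev <- two_comp_device(v1_uL = 200, v2_uL = 200)
  tr <- simulate_transport(dev, mod_species("x", 1e-9, c(A = 1)),
                           duration_s = 6.048e5,
                           output_times = c(0, 3600, 6.048e5))
  expect_equal(percent_transferred(tr, "A", "B", 0), 0)
  # equal volumes at equilibrium: half the mass sits in the target
  expect_equal(percent_transferred(tr, "A", "B", 6.048e5), 50,
               tolerance = 1e-4)
  expect_error(percent_transferred(tr, "B", "A", 3600),
               class = "organflux_undefined_metric")
  expect_error(percent_transferred(tr, "A", "B", 1234),
               class = "organflux_precondition_error")
})

test_that("fold_enhancement is exact on identities and flags overflow", {
  dev <- mod_device_default()
  sp <- tracer_species(dev, "dextran4", "POC", 1)
  times <- c(0, 3600, 10800)
  tr_f <- simulate_transport(dev, sp, flow_enabled = TRUE,
                             duration_s = 10800, output_times = times)
  tr_n <- simulate_transport(dev, sp, flow_enabled = FALSE,
                             duration_s = 10800, output_times = times)
  expect_equal(fold_enhancement(tr_f, tr_f, "LOC", "dextran4", 10800), 1)
  f1 <- fold_enhancement(tr_f, tr_n, "LOC", "dextran4", 10800)
  # scale invariance: doubling both loadings leaves the ratio unchanged
  sp2 <- tracer_species(dev, "dextran4", "POC", 2)
  tr_f2 <- simulate_transport(dev, sp2, flow_enabled = TRUE,
                              duration_s = 10800, output_times = times)
  tr_n2 <- simulate_transport(dev, sp2, flow_enabled = FALSE,
                              duration_s = 10800, output_times = times)
  expect_equal(fold_enhancement(tr_f2, tr_n2, "LOC", "dextran4", 10800), f1,
               tolerance = 1e-6)
  expect_error(fold_enhancement(tr_f, tr_n, "LOC", "dextran4", 0),
               class = "organflux_overflow")
  expect_error(fold_enhancement(tr_f, tr_n, "LOC", "glucose", 10800),
               class = "organflux_precondition_error")
})

test_that("transfer percent is non-decreasing in flow rate", {
  base <- mod_device_default()
  sp <- tracer_species(base, "dextran4", "POC", 1)
  rates <- c(0, 50, 200, 600, 1200)
  pct <- vapply(rates, function(r) {
    dev <- base
    dev$flow <- mod_flow(r, enabled = r > 0)
    tr <- simulate_transport(dev, sp, flow_enabled = r > 0,
                             duration_s = 10800,
                             output_times = c(0, 10800))
    percent_transferred(tr, "POC", c("CC", "LOC", "LOOP"), 10800)
  }, numeric(1))
  expect_true(all(diff(pct) >= -1e-8))
})

test_that("no-flow transfer ranks with diffusivity: glucose > 4 kDa > 70 kDa", {
  dev <- mod_device_default()
  pct <- vapply(c("glucose", "dextran4", "dextran70"), function(nm) {
    tr <- simulate_transport(dev, tracer_species(dev, nm, "POC", 1),
                             flow_enabled = FALSE, duration_s = 10800,
                             output_times = c(0, 10800))
    percent_transferred(tr, "POC", c("CC", "LOC", "LOOP"), 10800)
  }, numeric(1))
  expect_true(pct[["glucose"]] >= pct[["dextran4"]])
  expect_true(pct[["dextran4"]] >= pct[["dextran70"]])
})
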