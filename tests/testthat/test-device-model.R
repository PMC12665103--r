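test_that("wall shear stress reproduces the rectangular-channel estimate", {
  # Q = 0.01 cm3/s (600 uL/min), w = 0.7 cm, h = 0.3 cm, mu ~ 0.01 poise
  tau <- wall_shear_stress(mod_flow(600), mod_channel(0.7, 0.3),
                           mod_fluid(1000, 0.001))
  expect_equal(tau, 6 * 0.01 * 0.01 / (0.7 * 0.3^2), tolerance = 1e-12)
  expect_lt(abs(tau - 0.0095), 1e-4)
})

test_that("shear stress is zero without flow and scales as the closed form", {
  ch <- mod_channel(0.7, 0.3)
  fl <- mod_fluid(1000, 0.001)
  expect_identical(wall_shear_stress(mod_flow(0), ch, fl), 0)
  expect_identical(
    wall_shear_stress(mod_flow(600, enabled = FALSE), ch, fl), 0)
  set.seed(11)
  for (i in 1:20) {
    q <- runif(1, 10, 2000); w <- runif(1, 0.1, 2); h <- runif(1, 0.05, 1)
    mu <- runif(1, 5e-4, 5e-3)
    tau <- wall_shear_stress(mod_flow(q), mod_channel(w, h), mod_fluid(1000, mu))
    expect_equal(wall_shear_stress(mod_flow(2 * q), mod_channel(w, h),
                                   mod_fluid(1000, mu)), 2 * tau)
    expect_equal(wall_shear_stress(mod_flow(q), mod_channel(w, 2 * h),
                                   mod_fluid(1000, mu)), tau / 4)
    expect_equal(wall_shear_stress(mod_flow(q), mod_channel(2 * w, h),
                                   mod_fluid(1000, mu)), tau / 2)
    expect_equal(wall_shear_stress(mod_flow(q), mod_channel(w, h),
                                   mod_fluid(1000, 2 * mu)), 2 * tau)
  }
})

test_that("invalid geometry and fluid inputs are rejected", {
  expect_error(mod_channel(-0.7, 0.3), class = "organflux_geometry_error")
  expect_error(mod_channel(0.7, 0), class = "organflux_geometry_error")
  expect_error(mod_fluid(1000, -1), class = "organflux_fluid_error")
  expect_error(mod_membrane(porosity = 1.3), class = "organflux_membrane_error")
  expect_error(mod_membrane(porosity = 0), class = "organflux_membrane_error")
  expect_error(mod_membrane(tortuosity = 0.5),
               class = "organflux_membrane_error")
  expect_error(mod_flow(-10), class = "organflux_flow_error")
})

test_that("circulation time follows volume over rate", {
  expect_equal(circulation_time(600, mod_flow(600)), 1)
  expect_equal(circulation_time(300, mod_flow(600)), 0.5)
  expect_equal(circulation_time(600, mod_flow(1200)), 0.5)
  expect_error(circulation_time(600, mod_flow(0)),
               class = "organflux_undefined_circulation")
  expect_error(circulation_time(600, mod_flow(600, enabled = FALSE)),
               class = "organflux_undefined_circulation")
})

test_that("Darcy velocity follows (kappa/mu) dP/L with the sign of dP", {
  mem <- mod_membrane(kappa_m2 = 2.5e-14, thickness_um = 100)
  fl <- mod_fluid(1030, 0.0025)
  expect_identical(darcy_velocity(mem, fl, 0), 0)
  # direct arithmetic: (2.5e-14 / 0.0025) * (10 / 1e-4) = 1e-6 m/s
  expect_equal(darcy_velocity(mem, fl, 10), 1e-6, tolerance = 1e-12)
  expect_equal(darcy_velocity(mem, fl, -10), -1e-6, tolerance = 1e-12)
  mem2 <- mod_membrane(kappa_m2 = 5e-14, thickness_um = 100)
  expect_equal(darcy_velocity(mem2, fl, 10), 2 * darcy_velocity(mem, fl, 10))
})

test_that("membrane conductance matches the hand unit-conversion oracle", {
  # identity scaling: eps = 1, tau = 1, A = 1 cm^2, L = 1 cm, D = 1 cm^2/s
  mem <- mod_membrane(porosity = 1, thickness_um = 1e4, area_cm2 = 1,
                      tortuosity = 1)
  expect_equal(membrane_conductance(mem, 1e-4), 1, tolerance = 1e-12)
  # halving porosity halves conductance
  mem_half <- mod_membrane(porosity = 0.5, thickness_um = 1e4, area_cm2 = 1)
  expect_equal(membrane_conductance(mem_half, 1e-4), 0.5, tolerance = 1e-12)
  # the device membrane with the glucose diffusivity, against the frozen
  # hand-computed value 9.58e-6 * 0.8 * 1 / 5e-3 cm^3/s
  mem_dev <- mod_membrane(porosity = 0.8, thickness_um = 50, area_cm2 = 1)
  g <- membrane_conductance(mem_dev, 9.58e-10)
  expect_equal(g, 1.5328e-3, tolerance = 1e-9)
  expect_equal(g, conductance_oracle_cm3_s(9.58e-10, 0.8, 1, 50),
               tolerance = 1e-12)
})

test_that("conductance and Darcy velocity are homogeneous of degree 1", {
  set.seed(21)
  for (i in 1:10) {
    eps <- runif(1, 0.2, 1); a <- runif(1, 0.05, 3)
    l <- runif(1, 10, 200); tau <- runif(1, 1, 3); d <- 10^runif(1, -11, -9)
    g <- membrane_conductance(
      mod_membrane(porosity = eps, thickness_um = l, area_cm2 = a,
                   tortuosity = tau), d)
    g2 <- membrane_conductance(
      mod_membrane(porosity = eps, thickness_um = l, area_cm2 = 3 * a,
                   tortuosity = tau), d)
    expect_equal(g2, 3 * g, tolerance = 1e-12)
    g3 <- membrane_conductance(
      mod_membrane(porosity = eps, thickness_um = 2 * l, area_cm2 = a,
                   tortuosity = tau), d)
    expect_equal(g3, g / 2, tolerance = 1e-12)
  }
})

test_that("unit conversions round-trip to machine precision", {
  tab <- unit_conversion_table()
  x <- 1.2345
  for (i in seq_len(nrow(tab))) {
    back <- convert_units(convert_units(x, tab$from[i], tab$to[i]),
                          tab$to[i], tab$from[i])
    expect_equal(back, x, tolerance = 1e-12)
  }
  # converting the CGS shear inputs to SI and back leaves tau unchanged
  mu_si <- convert_units(0.01, "poise", "Pa.s")
  tau1 <- wall_shear_stress(mod_flow(600), mod_channel(0.7, 0.3),
                            mod_fluid(1000, mu_si))
  tau2 <- 6 * 0.01 * 0.01 / (0.7 * 0.09)
  expect_equal(tau1, tau2, tolerance = 1e-12)
  expect_error(convert_units(1, "uL", "furlong"),
               class = "organflux_unit_error")
})

test_that("device construction enforces topology invariants", {
  comp <- tibble::tibble(id = c("A", "B"), volume_uL = c(100, 100),
                         role = c("channel", "tubing"))
  # open convective path is rejected when flow is on
  expect_error(
    mod_device(comp, tibble::tibble(from = "A", to = "B"),
               membrane_row("A", "B", 0.1), flow = mod_flow(600)),
    class = "organflux_device_error")
  # closed loop is accepted
  dev <- mod_device(comp, tibble::tibble(from = c("A", "B"), to = c("B", "A")),
                    membrane_row("A", "B", 0.1), flow = mod_flow(600))
  expect_s3_class(dev, "mod_device")
  # duplicate ids, unknown references, non-positive volumes
  expect_error(mod_device(comp[c(1, 1), ], empty_edges(),
                          membrane_row("A", "A", 0.1)),
               class = "organflux_device_error")
  expect_error(mod_device(comp, empty_edges(), membrane_row("A", "Z", 0.1)),
               class = "organflux_device_error")
  comp_bad <- comp; comp_bad$volume_uL[1] <- 0
  expect_error(mod_device(comp_bad, empty_edges(),
                          membrane_row("A", "B", 0.1)),
               class = "organflux_device_error")
})
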