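test_that("parameter invariants are enforced before integration", {
  expect_error(gi_params(glucose_threshold = 2.5),
               class = "organflux_param_error")
  expect_error(gi_params(glucose_threshold = 21),
               class = "organflux_param_error")
  expect_error(gi_params(pa_secretion_factor = 1.2),
               class = "organflux_param_error")
  expect_error(gi_params(pa_uptake_factor = 0),
               class = "organflux_param_error")
  expect_error(gi_params(metformin_uptake_boost = 0.5),
               class = "organflux_param_error")
  expect_error(gi_params(uptake_rate = -1),
               class = "organflux_param_error")
})

test_that("no stimulus means flat trajectories at baseline", {
  dev <- mod_device_default()
  p <- gi_params(glucose_threshold = 6, uptake_rate = 0)
  res <- simulate_gtt(dev, p, "control", dose_mM = 0, duration_h = 6,
                      baseline_glucose_mM = 5.5)
  expect_equal(res$glucose_trajectory$value,
               rep(5.5, nrow(res$glucose_trajectory)), tolerance = 1e-6)
  expect_equal(res$insulin_trajectory$value,
               rep(p$basal_insulin, nrow(res$insulin_trajectory)),
               tolerance = 1e-6)
})

test_that("removing hepatic uptake raises the glucose AUC", {
  dev <- mod_device_default()
  res0 <- simulate_gtt(dev, gi_params(uptake_rate = 0), "control",
                       duration_h = 12)
  res1 <- simulate_gtt(dev, gi_params(uptake_rate = 0.05), "control",
                       duration_h = 12)
  expect_gt(res0$auc_glucose, res1$auc_glucose)
})

test_that("glucose and insulin stay non-negative and bounded", {
  dev <- mod_device_default()
  for (cond in c("control", "pa", "pa_metformin")) {
    res <- simulate_gtt(dev, gi_params(first_phase_amplitude = 10,
                                       sustained_rate = 5,
                                       uptake_rate = 0.2),
                        cond, duration_h = 24)
    expect_true(all(res$trajectories$value >= 0))
    expect_true(all(is.finite(res$trajectories$value)))
    expect_lt(max(res$trajectories$value[
      res$trajectories$variable == "glucose"]), 13 + 1e-6)
  }
})

test_that("insulin response to a glucose step is biphasic", {
  dev <- mod_device_default()
  res <- simulate_gtt(dev, gi_params(first_phase_amplitude = 2,
                                     sustained_rate = 1.5,
                                     uptake_rate = 0.05),
                      "control", duration_h = 24)
  ins <- res$insulin_trajectory
  peak_t <- ins$time_h[which.max(ins$value)]
  basal <- gi_params()$basal_insulin
  # early local maximum ...
  expect_lt(peak_t, 8)
  expect_gt(max(ins$value), ins$value[1] + 0.5)
  # ... followed by decline toward a sustained level above the start
  late <- ins$value[ins$time_h >= 20]
  expect_lt(max(late), max(ins$value))
})

test_that("trapezoid AUC matches closed forms", {
  const <- data.frame(t = seq(0, 10, 0.5), v = 3)
  expect_equal(trajectory_auc(const, 0, 10), 30)
  expect_equal(trajectory_auc(const, 0, 10, reference = 30), 1)
  # sampled sine over one period vs the analytic integral of sin^2-free form:
  # integral of (2 + sin t) over [0, 2*pi] = 4*pi
  tt <- seq(0, 2 * pi, length.out = 201)
  sine <- data.frame(t = tt, v = 2 + sin(tt))
  h <- diff(tt)[1]
  bound <- (2 * pi) * h^2 / 12 # trapezoid error bound, |f''| <= 1
  expect_lt(abs(trajectory_auc(sine, 0, 2 * pi) - 4 * pi), bound)
  expect_error(trajectory_auc(const, 5, 5),
               class = "organflux_precondition_error")
  expect_error(trajectory_auc(const, -1, 5),
               class = "organflux_precondition_error")
})

test_that("GSIS stimulation index responds to secretion parameters", {
  # secretion independent of glucose: index is exactly 1 each cycle
  p0 <- gi_params(first_phase_amplitude = 0, sustained_rate = 0)
  res0 <- gsis_protocol(p0, "control", cycles = 3)
  expect_equal(res0$stimulation_index, rep(1, 3))
  expect_true(all(res0$insulin_low > 0))
  # palmitate with a sub-unity secretion factor lowers the index
  p <- gi_params(first_phase_amplitude = 2, sustained_rate = 1.5,
                 pa_secretion_factor = 0.6)
  ctrl <- gsis_protocol(p, "control", cycles = 3)
  pa <- gsis_protocol(p, "pa", cycles = 3)
  expect_true(all(pa$stimulation_index < ctrl$stimulation_index))
  expect_true(all(ctrl$stimulation_index > 1))
  expect_error(gsis_protocol(p, "control", cycles = 0),
               class = "organflux_precondition_error")
})

test_that("condition factors compose as declared", {
  p <- gi_params(pa_secretion_factor = 0.8, pa_uptake_factor = 0.1,
                 metformin_uptake_boost = 5, metformin_secretion_boost = 1.1)
  f_pa <- organflux:::condition_factors(p, "pa")
  expect_equal(unname(f_pa), c(0.8, 0.1))
  f_met <- organflux:::condition_factors(p, "pa_metformin")
  expect_equal(f_met[["fu"]], 0.5)
  expect_equal(f_met[["fs"]], min(0.8 * 1.1, 1))
})
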