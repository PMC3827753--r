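test_that("generators are seed-deterministic", {
  p <- gait_parameters(duration = 3)
  g1 <- generate_gait(p, compute_truth = FALSE)
  g2 <- generate_gait(p, compute_truth = FALSE)
  expect_identical(g1$trajectories$markers, g2$trajectories$markers)
  c1 <- generate_vo2_cohort(seed = 8)
  c2 <- generate_vo2_cohort(seed = 8)
  expect_identical(c1, c2)
  expect_identical(generate_runner_cohort(seed = 4),
                   generate_runner_cohort(seed = 4))
})

test_that("gait parameter validation", {
  expect_error(gait_parameters(stride_frequency = 0), "stride_frequency")
  expect_error(gait_parameters(duration = 0.5), "two strides")
  expect_error(gait_parameters(marker_noise_sd = -1), "noise")
})

test_that("the oracle is self-consistent under grid refinement", {
  p <- gait_parameters(marker_noise_sd = 0)
  w1 <- oracle_gait_work(p, grid_rate = 5000)
  w2 <- oracle_gait_work(p, grid_rate = 10000)
  expect_lt(abs(w1$W_int_abs / w2$W_int_abs - 1), 0.001)
  expect_lt(abs(w1$W_ext_abs / w2$W_ext_abs - 1), 0.001)
})

test_that("a static body performs no mechanical work", {
  p <- static_params()
  w <- oracle_gait_work(p)
  expect_equal(w$W_int_abs, 0)
  expect_equal(w$W_ext_abs, 0)
  traj <- static_trajectories()
  wk <- compute_work(traj, default_model(), window = full_window(traj))
  expect_equal(wk$W_int_abs, 0)
  expect_equal(wk$W_ext_abs, 0)
  expect_equal(wk$W_tot_abs, 0)
})

test_that("a bouncing rigid body does external work only", {
  p <- gait_parameters(thigh_amplitude = 0, knee_amplitude = 0,
                       foot_amplitude = 0, trunk_pitch_amplitude = 0,
                       arm_amplitude = 0, forearm_amplitude = 0,
                       marker_noise_sd = 0)
  w <- oracle_gait_work(p)
  expect_equal(w$W_int_abs, 0, tolerance = 1e-9)
  expect_gt(w$W_ext_abs, 0)
  g <- generate_gait(p, compute_truth = FALSE)
  wk <- compute_work(g$trajectories, default_model())
  expect_lt(wk$W_int_abs, 0.005 * wk$W_ext_abs)
  expect_equal(wk$W_ext_abs / wk$duration,
               w$W_ext_abs * p$stride_frequency / 5, tolerance = 0.005)
})

test_that("the default gait works external-dominant, as in running", {
  tw <- clean_gait()$truth$work
  expect_gt(tw$W_ext_abs, tw$W_int_abs)
  wk <- clean_work()
  expect_gt(wk$W_ext_abs, wk$W_int_abs)
})

test_that("VO2 cohorts follow the requested power law", {
  c0 <- generate_vo2_cohort(log_noise_sd = 0, seed = 12)
  f <- fit_allometric(c0$body_mass_kg, c0$vo2max_abs_ml_min)
  expect_equal(f$b, 0.49, tolerance = 1e-9)
  expect_equal(f$a, 454, tolerance = 1e-6)
  expect_true(all(c0$body_mass_kg > 40))
  expect_error(generate_vo2_cohort(n = 2), "at least 3")
})

test_that("runner cohorts are internally consistent", {
  cohort <- generate_runner_cohort(n = 14, seed = 2)
  expect_equal(cohort$w_tot, cohort$w_int + cohort$w_ext)
  expect_true(all(cohort$w_int > 0 & cohort$w_ext > 0))
  expect_true(all(cohort$body_mass_kg > 40))
  expect_equal(nrow(cohort), 14)
})
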