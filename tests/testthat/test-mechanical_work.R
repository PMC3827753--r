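# hand-built kinematics/model pairs for unit-level energy tests
fake_two_segment <- function(E1, E2, same_limb) {
  n <- length(E1)
  seg <- function(E) list(mass = 1, K = 0,
                          v = cbind(sqrt(2 * E), 0),
                          v_rel = cbind(sqrt(2 * E), 0),
                          omega = rep(0, n))
  kin <- structure(
    list(sample_rate = 100, n_frames = n,
         segments = list(a = seg(E1), b = seg(E2)),
         total_mass = 2, g = 9.81),
    class = "segment_kinematics")
  model <- structure(
    list(segments = data.frame(
      name = c("a", "b"),
      group = if (same_limb) c("limb1", "limb1") else c("limb1", "limb2"),
      stringsAsFactors = FALSE)),
    class = "body_model")
  list(kin = kin, model = model)
}

test_that("relative kinetic energy formula", {
  expect_equal(ke_relative(1, 0, 0, 0.1, 0), 0)
  expect_equal(ke_relative(2, 1, 0, 0, 0), 1)
  expect_equal(ke_relative(4.5, 0.3, 0.1, 0.12, 5), 1.035)
  # vectorised over frames
  expect_equal(ke_relative(2, c(1, 2), c(0, 0), 0, c(0, 0)), c(1, 4))
  expect_error(ke_relative(-1, 0, 0, 0, 0), "positive")
  expect_error(ke_relative(1, 0, 0, -0.1, 0), "gyration")
})

test_that("positive increments: only rises count", {
  expect_equal(positive_increments(c(5, 4, 3, 2)), 0)
  expect_equal(positive_increments(c(0, 1, 0, 1, 0)), 2)
  # A sin over k whole cycles rises 2A per cycle
  fs <- 240; A <- 3; k <- 4
  t <- seq(0, k / 2, by = 1 / fs)  # 2 Hz -> k cycles
  expect_equal(positive_increments(A * sin(2 * pi * 2 * t)), 2 * A * k,
               tolerance = 1e-3)
  w <- stride_window(2, 4, 1, fs)
  expect_equal(positive_increments(c(9, 0, 1, 0, 9), w), 1)
  expect_error(positive_increments(1:10, stride_window(8, 20, 1, fs)),
               "exceeds")
})

test_that("within-limb energy transfer: sum first, then increments", {
  t <- seq(0, 2, by = 0.01)
  E1 <- 1 + sin(2 * pi * t)
  E2 <- 1 - sin(2 * pi * t)
  w <- stride_window(1, length(t), 1, 100)
  same <- fake_two_segment(E1, E2, same_limb = TRUE)
  diff_ <- fake_two_segment(E1, E2, same_limb = FALSE)
  expect_equal(segment_energies(same$kin)[, "a"], E1)
  wi_same <- internal_work(same$kin, same$model, w)
  wi_diff <- internal_work(diff_$kin, diff_$model, w)
  # perfectly anti-phase energies cancel inside one limb ...
  expect_equal(wi_same$total, 0, tolerance = 1e-9)
  # ... but not across limbs, where no transfer is allowed
  expect_gt(wi_diff$total, 3.9)
  expect_named(wi_diff$per_limb, c("limb1", "limb2"))
})

test_that("external work vanishes for constant energy and pendular exchange", {
  n <- 1001
  M <- 70; g <- 9.81
  mk_kin <- function(h, v_ap, v_v) structure(
    list(com = list(h = h, v_belt = cbind(v_ap, v_v)),
         total_mass = M, g = g, n_frames = length(h)),
    class = "segment_kinematics")
  w <- stride_window(1, n, 1, 100)
  # constant height and speed
  ce <- com_energy(mk_kin(rep(1, n), rep(3, n), rep(0, n)))
  expect_equal(external_work(ce, w), 0)
  # anti-phase PE and KE of equal amplitude (walking-like): E_CM constant
  t <- seq(0, 2, length.out = n)
  h <- 1 + 0.03 * sin(2 * pi * t)
  v_ap <- sqrt(3^2 - 2 * g * 0.03 * sin(2 * pi * t))
  ce2 <- com_energy(mk_kin(h, v_ap, rep(0, n)))
  expect_equal(diff(range(ce2$E_CM)), 0, tolerance = 1e-9)
  expect_equal(external_work(ce2, w), 0, tolerance = 1e-6)
  expect_equal(ce2$E_CM, ce2$PE + ce2$KE_ap + ce2$KE_v)
})

test_that("external work of a bouncing centre of mass matches a dense oracle", {
  M <- 70; g <- 9.81; A <- 0.05; f <- 1.4; k <- 5
  E_of <- function(t) {
    h <- 1 + A * sin(2 * pi * f * t)
    v_v <- A * 2 * pi * f * cos(2 * pi * f * t)
    M * g * h + 0.5 * M * 3.1^2 + 0.5 * M * v_v^2
  }
  coarse <- E_of(seq(0, k / f, by = 1 / 240))
  dense <- E_of(seq(0, k / f, by = 1 / 10000))
  expect_equal(positive_increments(coarse) / positive_increments(dense), 1,
               tolerance = 0.005)
})

test_that("total work is the arithmetic sum, including the study's means", {
  expect_equal(total_work(0, 5), 5)
  expect_equal(total_work(0.63, 1.22), 1.85)          # b = 1 group means
  expect_equal(total_work(5.43, 10.53), 15.96)        # b = 0.49 group means
  expect_error(total_work(-0.1, 1), "non-negative")
})

test_that("Koenig residual vanishes for arbitrary consistent kinematics", {
  model <- default_model()
  for (seed in 1:5) {
    kin <- compute_segment_kinematics(random_trajectories(seed = seed), model)
    kr <- koenig_residual(kin)
    expect_lt(max(abs(kr$relative)), 1e-9)
  }
})

test_that("work normalisation algebra", {
  expect_equal(normalize_work(100, 1, 1, 100), 1)
  expect_equal(normalize_work(100, 70, 0, 10), normalize_work(100, 5, 0, 10))
  expect_equal(normalize_work(80, 70, 0.75, 11),
               normalize_work(80, 70, 1, 11) * 70^0.25)
  expect_error(normalize_work(1, 0, 1, 1), "mass")
  expect_error(normalize_work(1, 70, 1, 0), "distance")
})

test_that("work results obey the structural invariants", {
  wk <- clean_work()
  expect_gte(wk$W_int_abs, 0)
  expect_gte(wk$W_ext_abs, 0)
  expect_equal(wk$W_tot_abs, wk$W_int_abs + wk$W_ext_abs)
  expect_equal(wk$W_int_abs, sum(wk$per_limb))
  expect_equal(wk$normalized$W_tot, wk$normalized$W_int + wk$normalized$W_ext)
  expect_equal(wk$normalized$W_int,
               wk$W_int_abs / (wk$M^wk$normalized$b * wk$distance))
})

test_that("works are invariant to the height datum and W_int to belt speed", {
  g <- clean_gait()
  model <- default_model()
  wk <- clean_work()
  # shift every marker up by 10 m: PE offset cancels in the increments
  up <- g$trajectories
  up$markers <- lapply(up$markers, function(m) {
    m[, 2] <- m[, 2] + 10; m
  })
  wk_up <- compute_work(up, model)
  expect_equal(wk_up$W_ext_abs, wk$W_ext_abs, tolerance = 1e-6)
  expect_equal(wk_up$W_int_abs, wk$W_int_abs, tolerance = 1e-9)
  # belt speed does not touch relative velocities
  lab <- g$trajectories
  lab$belt_speed <- 0
  wk_lab <- compute_work(lab, model, window = wk$window)
  expect_equal(wk_lab$W_int_abs, wk$W_int_abs, tolerance = 1e-12)
})

test_that("doubling body mass doubles absolute works, b = 1 values unchanged", {
  g <- clean_gait()
  wk <- clean_work()
  heavy <- build_body_model(140, 1.71)
  wk2 <- compute_work(g$trajectories, heavy, window = wk$window)
  expect_equal(wk2$W_int_abs, 2 * wk$W_int_abs, tolerance = 1e-9)
  expect_equal(wk2$W_ext_abs, 2 * wk$W_ext_abs, tolerance = 1e-9)
  b1 <- wk$normalized$b == 1
  expect_equal(wk2$normalized$W_tot[b1], wk$normalized$W_tot[b1],
               tolerance = 1e-9)
})
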