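fs <- 240

test_that("zero-lag Butterworth: DC gain 1, passband flat, stopband strong", {
  expect_equal(lowpass_filter(rep(2.5, 480), 10, fs), rep(2.5, 480))
  t <- (0:(4 * fs - 1)) / fs
  mid <- (fs + 1):(3 * fs)  # keep clear of the record edges
  y1 <- lowpass_filter(sin(2 * pi * 1 * t), 10, fs)
  expect_gt(max(abs(y1[mid])), 0.99)           # < 1% passband attenuation
  y60 <- lowpass_filter(sin(2 * pi * 60 * t), 10, fs)
  # zero-phase 4th-order magnitude at 6x cutoff is 1/(1 + 6^4) ~ 7.7e-4
  expect_lt(max(abs(y60[mid])), 0.05)          # > 95% attenuation
  expect_error(lowpass_filter(t, 0, fs), "cutoff")
  expect_error(lowpass_filter(t, 130, fs), "cutoff")
})

test_that("filtering is idempotent to < 0.5% for passband signals", {
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 1.4 * t) + 0.3 * sin(2 * pi * 2.8 * t)
  y1 <- lowpass_filter(x, 8, fs)
  y2 <- lowpass_filter(y1, 8, fs)
  mid <- (fs + 1):(3 * fs)
  expect_lt(max(abs(y2[mid] - y1[mid])) / max(abs(y1[mid])), 0.005)
})

test_that("numerical differentiation is exact on linears, accurate on sines", {
  expect_equal(differentiate(2 * (0:99) / fs, fs), rep(2, 100))
  expect_equal(differentiate(rep(7, 50), fs), rep(0, 50))
  t <- (0:(2 * fs)) / fs
  d <- differentiate(sin(2 * pi * t), fs)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(d[interior] - 2 * pi * cos(2 * pi * t[interior]))), 1e-3)
  expect_error(differentiate(c(1, 2), fs), "length")
})

test_that("automatic cut-off selection clamps to 8-11 Hz and is deterministic", {
  t <- (0:(5 * fs - 1)) / fs
  pure <- 0.05 * sin(2 * pi * 2 * t)
  traj <- marker_trajectories(
    list(a = cbind(pure, pure), b = cbind(pure, pure)), fs)
  fc <- auto_cutoff(traj)
  expect_equal(unname(fc[["a"]]), 8)           # lower clamp
  expect_equal(fc[["a"]], fc[["b"]])           # identical markers, same choice
  set.seed(7)
  noisy <- pure + rnorm(length(t), 0, 0.02)
  fc2 <- auto_cutoff(marker_trajectories(list(a = cbind(noisy, noisy)), fs))
  expect_gte(fc2[["a"]], 8)
  expect_lte(fc2[["a"]], 11)
  expect_error(
    auto_cutoff(marker_trajectories(list(a = cbind(pure, pure)), 20)),
    "Nyquist")
})

test_that("marker files round-trip, small gaps interpolate, large gaps abort", {
  g <- clean_gait()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_markers(g$trajectories, path)
  back <- load_markers(path, fs, belt_speed = 3.1)
  expect_equal(back$markers, g$trajectories$markers, tolerance = 1e-12)
  expect_equal(back$duration, g$trajectories$duration)
  # one-frame gap: interpolated with a warning
  tab <- read.delim(path)
  tab$hip_y[100] <- NA
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(tr <- load_markers(path, fs), "interpolated")
  expect_equal(unname(tr$markers$hip[100, "y"]),
               mean(tr$markers$hip[c(99, 101), "y"]))
  # 100-frame gap: load error naming the frame
  tab$hip_y[200:299] <- NA
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_markers(path, fs), "frame 200")
  expect_error(load_markers(withr::local_tempfile(fileext = ".tsv"), fs),
               "not found")
})

test_that("stride detection finds the last n strides at the right period", {
  p <- gait_parameters(marker_noise_sd = 0, duration = 10)
  g <- generate_gait(p, compute_truth = FALSE)
  sw <- detect_strides(filter_trajectories(g$trajectories, 8), n_strides = 5)
  expect_equal(sw$n_strides, 5)
  # stride period recovered within one frame of 1/1.4 s
  expect_lt(abs(sw$stride_period - 1 / 1.4), 1 / fs)
  expect_equal(length(sw$boundaries), 6)
  # boundaries sit at local minima of the heel height as the detector sees
  # it (its own 8 Hz smoothing on top of the input)
  y <- lowpass_filter(
    filter_trajectories(g$trajectories, 8)$markers$heel_L[, "y"], 8, fs)
  inner <- sw$boundaries[sw$boundaries > 1 & sw$boundaries < length(y)]
  expect_true(all(y[inner] <= y[inner - 1] & y[inner] <= y[inner + 1]))
  # more strides than the record holds
  expect_error(detect_strides(g$trajectories, n_strides = 30), "stride")
  # non-periodic noise is rejected
  set.seed(1)
  noise <- marker_trajectories(
    list(heel_L = cbind(rnorm(5 * fs), rnorm(5 * fs))), fs)
  expect_error(detect_strides(noise), "periodic")
})

test_that("contralateral mirroring is a half-stride shift", {
  # 1.5 Hz stride at 240 Hz: half a stride is exactly 80 frames
  p <- gait_parameters(stride_frequency = 1.5, marker_noise_sd = 0,
                       duration = 6)
  g <- generate_gait(p, compute_truth = FALSE)
  mir <- mirror_contralateral(g$trajectories, 1 / 1.5)
  for (nm in names(g$truth$right))
    expect_lt(max(abs(mir$markers[[nm]] - g$truth$right[[nm]])), 1e-9)
  # constant trajectories mirror to identical copies
  st <- static_trajectories()
  keep <- grep("_R$", names(st$markers), invert = TRUE, value = TRUE)
  st$markers <- st$markers[keep]
  mir2 <- mirror_contralateral(st, 0.5)
  expect_equal(mir2$markers$ankle_R, unname(st$markers$ankle_L),
               ignore_attr = TRUE)
  expect_error(mirror_contralateral(st, -1), "positive")
})

test_that("segment kinematics: static body is at rest, translation is rigid", {
  model <- default_model()
  st <- static_trajectories()
  kin <- compute_segment_kinematics(st, model)
  for (s in kin$segments) {
    expect_equal(max(abs(s$v)), 0)
    expect_equal(max(abs(s$omega)), 0)
    expect_equal(max(abs(s$v_rel)), 0)
  }
  tr <- static_trajectories(velocity = c(1, 0))
  kin2 <- compute_segment_kinematics(tr, model)
  expect_equal(kin2$com$v_lab[, 1], rep(1, tr$n_frames), tolerance = 1e-9)
  expect_equal(max(abs(kin2$com$v_lab[, 2])), 0, tolerance = 1e-9)
  for (s in kin2$segments)
    expect_lt(max(abs(s$v_rel)), 1e-9)
})

test_that("mass-weighted relative velocities vanish at every frame", {
  model <- default_model()
  for (traj in list(random_trajectories(seed = 3),
                    mirror_contralateral(clean_gait()$trajectories, 1 / 1.4))) {
    kin <- compute_segment_kinematics(traj, model)
    acc <- matrix(0, kin$n_frames, 2)
    for (s in kin$segments) acc <- acc + s$mass * s$v_rel
    expect_lt(max(abs(acc)), 1e-9)
  }
})

test_that("belt-frame forward velocity averages to the belt speed", {
  g <- clean_gait()
  kin <- compute_segment_kinematics(
    mirror_contralateral(filter_trajectories(g$trajectories, 8), 1 / 1.4),
    default_model())
  expect_lt(abs(mean(kin$com$v_belt[, 1]) / 3.1 - 1), 0.05)
})
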