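# Shared fixtures, built once per test run.  All synthetic; nothing on disk.

.fixtures <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- build_body_model(70, 1.71)
  .fixtures$model
}

# noise-free default gait with oracle ground truth
clean_gait <- function() {
  if (is.null(.fixtures$gait))
    .fixtures$gait <- generate_gait(gait_parameters(marker_noise_sd = 0))
  .fixtures$gait
}

# pipeline work result on the clean gait
clean_work <- function() {
  if (is.null(.fixtures$work))
    .fixtures$work <- compute_work(clean_gait()$trajectories, default_model())
  .fixtures$work
}

# all amplitudes zero: a static standing body
static_params <- function(duration = 2, belt_speed = 0) {
  gait_parameters(belt_speed = belt_speed, com_vertical_amplitude = 0,
                  com_ap_amplitude = 0, thigh_amplitude = 0,
                  knee_amplitude = 0, foot_amplitude = 0,
                  trunk_pitch_amplitude = 0, arm_amplitude = 0,
                  forearm_amplitude = 0, marker_noise_sd = 0,
                  duration = duration)
}

# full 16-marker static pose (both sides), optionally translating rigidly
static_trajectories <- function(duration = 2, fs = 240, velocity = c(0, 0),
                                belt_speed = 0) {
  p <- static_params(duration = duration, belt_speed = belt_speed)
  t <- (seq_len(round(duration * fs)) - 1) / fs
  mk <- gait_marker_positions(p, t)
  mk <- lapply(mk, function(m)
    m + cbind(velocity[1] * t, velocity[2] * t))
  marker_trajectories(mk, fs, belt_speed)
}

# smooth random marker set covering the full model (for identity checks)
random_trajectories <- function(n = 200, fs = 240, seed = 1) {
  set.seed(seed)
  nm <- model_markers(default_model())
  mk <- lapply(seq_along(nm), function(i) {
    cbind(cumsum(rnorm(n, 0, 0.01)), 1 + cumsum(rnorm(n, 0, 0.01)))
  })
  names(mk) <- nm
  marker_trajectories(mk, fs, 0)
}

full_window <- function(traj, n_strides = 1) {
  stride_window(1, traj$n_frames, n_strides, traj$sample_rate)
}
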