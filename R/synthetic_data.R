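#' Parameters of the synthetic running gait
#'
#' Defines a deliberately simple, fully analytic treadmill running gait:
#' the pelvis oscillates vertically as `h0 + A sin(2 pi f t)` at the stride
#' frequency `f` while advancing at zero mean velocity in the camera frame
#' (the belt supplies the progression speed), and the limb segment angles
#' are sinusoids at the stride frequency with fixed amplitudes and phases.
#' Right-side trajectories are the left side delayed by half a stride.
#' Because all prescribed oscillations sit at the stride frequency, segment
#' energies have near-closed forms and a dense-grid numerical oracle can
#' certify the work computation; realism of the waveforms is explicitly a
#' non-goal.
#'
#' Defaults emulate the study conditions of a treadmill running-economy
#' trial: belt speed 3.1 m s^-1, capture at 240 Hz for 20 s, body mass
#' 70 kg, stature 1.71 m, a stride frequency of 1.4 Hz (typical at this
#' speed), pelvis vertical amplitude 5 cm with the forward-velocity
#' fluctuation in phase with it (the in-phase energy fluctuation that
#' distinguishes bouncing from pendular gaits), thigh swing 0.35 rad with a
#' slight forward mean, knee flexion 0.45 +/- 0.35 rad a quarter-cycle out
#' of phase (which breaks half-stride symmetry, as stance/swing asymmetry
#' does in real gait), arm swing in anti-phase with the ipsilateral leg,
#' and additive Gaussian marker noise of 2 mm emulating digitisation error.
#'
#' @param belt_speed Treadmill belt speed, m s^-1.
#' @param stride_frequency Stride (full gait cycle) frequency, Hz.
#' @param com_vertical_amplitude Pelvis vertical oscillation amplitude, m.
#' @param com_ap_amplitude Pelvis antero-posterior oscillation amplitude, m.
#' @param ap_phase Phase of the antero-posterior oscillation, rad.
#' @param thigh_offset,thigh_amplitude Mean and amplitude of the thigh
#'   angle from the downward vertical, rad.
#' @param knee_mean,knee_amplitude,knee_phase Knee flexion sinusoid, rad.
#' @param foot_angle,foot_amplitude,foot_phase Foot segment angle from the
#'   downward vertical, rad.
#' @param trunk_lean,trunk_pitch_amplitude Trunk inclination from vertical:
#'   mean and oscillation amplitude, rad.
#' @param arm_amplitude Upper-arm swing amplitude, rad (anti-phase to the
#'   ipsilateral thigh).
#' @param elbow_flexion Fixed elbow flexion carrying the forearm, rad.
#' @param forearm_amplitude Additional forearm swing amplitude, rad.
#' @param body_mass Body mass, kg.
#' @param body_height Stature, m.
#' @param sample_rate Capture rate, Hz.
#' @param duration Record length, s.
#' @param marker_noise_sd Additive marker noise standard deviation, m.
#' @param seed Integer seed for the noise.
#' @return An object of class `gait_parameters`.
#' @export
gait_parameters <- function(belt_speed = 3.1, stride_frequency = 1.4,
                            com_vertical_amplitude = 0.05,
                            com_ap_amplitude = 0.015, ap_phase = -pi / 2,
                            thigh_offset = 0.12, thigh_amplitude = 0.35,
                            knee_mean = 0.45, knee_amplitude = 0.35,
                            knee_phase = -pi / 2,
                            foot_angle = 1.35, foot_amplitude = 0.25,
                            foot_phase = pi / 2,
                            trunk_lean = 0.05, trunk_pitch_amplitude = 0.03,
                            arm_amplitude = 0.25, elbow_flexion = 1.2,
                            forearm_amplitude = 0.10,
                            body_mass = 70, body_height = 1.71,
                            sample_rate = 240, duration = 20,
                            marker_noise_sd = 0.002, seed = 1L) {
  p <- list(belt_speed = belt_speed, stride_frequency = stride_frequency,
            com_vertical_amplitude = com_vertical_amplitude,
            com_ap_amplitude = com_ap_amplitude, ap_phase = ap_phase,
            thigh_offset = thigh_offset, thigh_amplitude = thigh_amplitude,
            knee_mean = knee_mean, knee_amplitude = knee_amplitude,
            knee_phase = knee_phase, foot_angle = foot_angle,
            foot_amplitude = foot_amplitude, foot_phase = foot_phase,
            trunk_lean = trunk_lean,
            trunk_pitch_amplitude = trunk_pitch_amplitude,
            arm_amplitude = arm_amplitude, elbow_flexion = elbow_flexion,
            forearm_amplitude = forearm_amplitude,
            body_mass = body_mass, body_height = body_height,
            sample_rate = sample_rate, duration = duration,
            marker_noise_sd = marker_noise_sd, seed = as.integer(seed))
  must_pos <- c("belt_speed", "stride_frequency", "body_mass", "body_height",
                "sample_rate", "duration")
  for (nm in must_pos)
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop(nm, " must be non-negative")
  if (p$stride_frequency <= 0) stop("stride_frequency must be positive")
  if (p$marker_noise_sd < 0) stop("marker_noise_sd must be non-negative")
  if (p$duration < 2 / p$stride_frequency)
    stop("duration must cover at least two strides")
  class(p) <- "gait_parameters"
  p
}

# rotation of a 2-vector by angle d (vectorised over d)
rot2 <- function(v, d) {
  cbind(cos(d) * v[1] - sin(d) * v[2], sin(d) * v[1] + cos(d) * v[2])
}

#' Analytic marker positions of the synthetic gait
#'
#' Evaluates the parametric gait model at arbitrary times, for both the
#' filmed (left) and the contralateral (right) side; the right side is the
#' left side delayed by half a stride period.  This is the ground-truth
#' function behind both [generate_gait()] (which samples it at the capture
#' rate) and [oracle_gait_work()] (which samples it on a dense grid).
#'
#' @param p A [gait_parameters()] object.
#' @param t Numeric vector of times, s.
#' @param sides Sides to emit (`"L"`, `"R"` or both).
#' @return Named list of `length(t) x 2` matrices: markers `head`, `hip`
#'   and, per side, `shoulder`, `elbow`, `wrist`, `knee`, `ankle`, `heel`,
#'   `toe`.
#' @export
gait_marker_positions <- function(p, t, sides = c("L", "R")) {
  stopifnot(inherits(p, "gait_parameters"))
  H <- p$body_height
  w <- 2 * pi * p$stride_frequency
  L_th <- 0.245 * H; L_sh <- 0.246 * H; L_ft <- 0.152 * H
  L_ua <- 0.186 * H; L_fa <- 0.146 * H
  L_trunk <- 0.47 * H; L_shoulder <- 0.37 * H
  hip_h <- 0.53 * H
  heel_local <- c(-0.035 * H, -0.02 * H)
  side_chain <- function(tt) {
    lam <- p$trunk_lean + p$trunk_pitch_amplitude * sin(w * tt + pi)
    hip <- cbind(p$com_ap_amplitude * sin(w * tt + p$ap_phase),
                 hip_h + p$com_vertical_amplitude * sin(w * tt))
    tdir <- cbind(sin(lam), cos(lam))
    th <- p$thigh_offset + p$thigh_amplitude * sin(w * tt)
    knee <- hip + L_th * cbind(sin(th), -cos(th))
    kappa <- p$knee_mean + p$knee_amplitude * sin(w * tt + p$knee_phase)
    sh <- th - kappa
    ankle <- knee + L_sh * cbind(sin(sh), -cos(sh))
    af <- p$foot_angle + p$foot_amplitude * sin(w * tt + p$foot_phase)
    toe <- ankle + L_ft * cbind(sin(af), -cos(af))
    heel <- ankle + rot2(heel_local, af - p$foot_angle)
    shoulder <- hip + L_shoulder * tdir
    ua <- -0.05 + p$arm_amplitude * sin(w * tt + pi)
    elbow <- shoulder + L_ua * cbind(sin(ua), -cos(ua))
    fa <- ua + p$elbow_flexion + p$forearm_amplitude * sin(w * tt + pi)
    wrist <- elbow + L_fa * cbind(sin(fa), -cos(fa))
    list(hip = hip, head = hip + L_trunk * tdir, shoulder = shoulder,
         elbow = elbow, wrist = wrist, knee = knee, ankle = ankle,
         heel = heel, toe = toe)
  }
  lab <- function(m) { colnames(m) <- c("x", "y"); m }
  out <- list()
  left <- side_chain(t)
  if ("L" %in% sides) {
    out$head <- lab(left$head)
    out$hip <- lab(left$hip)
    for (nm in c("shoulder", "elbow", "wrist", "knee", "ankle", "heel",
                 "toe"))
      out[[paste0(nm, "_L")]] <- lab(left[[nm]])
  }
  if ("R" %in% sides) {
    # pelvis-anchored half-stride delay: the limb chain is evaluated half a
    # stride ago but re-attached to the pelvis at the current time, exactly
    # as mirror_contralateral() reconstructs the unfilmed side
    shifted <- side_chain(t - 0.5 / p$stride_frequency)
    if (!("L" %in% sides)) {
      out$head <- lab(left$head)
      out$hip <- lab(left$hip)
    }
    for (nm in c("shoulder", "elbow", "wrist", "knee", "ankle", "heel",
                 "toe"))
      out[[paste0(nm, "_R")]] <- lab(left$hip + shifted[[nm]] - shifted$hip)
  }
  out
}

#' Generate a synthetic running gait with ground truth
#'
#' Samples the analytic gait at the capture rate, adds seeded Gaussian
#' marker noise to the nine left-side markers, and attaches a ground-truth
#' record: the noise-free right-side trajectories (for validating the
#' half-stride contralateral reconstruction), the stride period, and the
#' internal/external/total work computed by the dense-grid brute-force
#' oracle on the noise-free analytic gait.
#'
#' @param p A [gait_parameters()] object.
#' @param n_strides Strides the ground-truth works are accumulated over.
#' @param compute_truth If `FALSE`, skip the (comparatively costly) oracle.
#' @param oracle_rate Dense grid rate for the oracle, Hz.
#' @return A list of class `synthetic_gait`: `trajectories` (the nine-marker
#'   left-side [marker_trajectories()]), `truth` (list: `stride_period`,
#'   `right`, and `work` from [oracle_gait_work()]), and `parameters`.
#' @export
generate_gait <- function(p, n_strides = 5, compute_truth = TRUE,
                          oracle_rate = 10000) {
  stopifnot(inherits(p, "gait_parameters"))
  n <- round(p$duration * p$sample_rate)
  t <- (seq_len(n) - 1) / p$sample_rate
  mk <- gait_marker_positions(p, t)
  left_names <- c("head", "hip", paste0(c("shoulder", "elbow", "wrist",
                                          "knee", "ankle", "heel", "toe"),
                                        "_L"))
  left <- mk[left_names]
  if (p$marker_noise_sd > 0) {
    set.seed(p$seed)
    left <- lapply(left, function(m)
      m + matrix(stats::rnorm(length(m), 0, p$marker_noise_sd), nrow(m), 2))
  }
  truth <- list(stride_period = 1 / p$stride_frequency,
                right = mk[grep("_R$", names(mk), value = TRUE)])
  if (compute_truth)
    truth$work <- oracle_gait_work(p, n_strides = n_strides,
                                   grid_rate = oracle_rate)
  structure(
    list(trajectories = marker_trajectories(left, p$sample_rate,
                                            p$belt_speed),
         truth = truth, parameters = p),
    class = "synthetic_gait")
}

#' Dense-grid brute-force work oracle for the analytic gait
#'
#' Computes the ground-truth internal and external work of the synthetic
#' gait directly from the analytic (noise-free) marker functions: positions
#' are evaluated on a dense time grid (default 10 kHz) spanning exactly
#' `n_strides` stride periods, velocities and angular velocities are taken
#' by central differences on that grid, and positive energy increments are
#' summed without any filtering or event detection.  This is deliberately
#' independent of the measurement pipeline (no Butterworth filter, no
#' stride segmentation, no contralateral reconstruction from data) and
#' serves as the reference the pipeline is validated against.
#'
#' @param p A [gait_parameters()] object.
#' @param model Optional [build_body_model()]; defaults to the Winter model
#'   at the gait's mass and height.
#' @param n_strides Number of stride periods to integrate over.
#' @param grid_rate Dense grid rate, Hz.
#' @param b_values Allometric exponents for the normalised works.
#' @return List with `W_int_abs`, `W_ext_abs`, `W_tot_abs`, `per_limb`,
#'   `distance`, `normalized` (or `NULL` when the belt speed is zero),
#'   `n_strides` and `grid_rate`.
#' @export
oracle_gait_work <- function(p, model = NULL, n_strides = 5,
                             grid_rate = 10000, b_values = c(1, 0.75)) {
  stopifnot(inherits(p, "gait_parameters"))
  if (is.null(model))
    model <- build_body_model(p$body_mass, p$body_height)
  Tp <- 1 / p$stride_frequency
  N <- round(n_strides * Tp * grid_rate)
  dt <- n_strides * Tp / N
  t <- (-1:(N + 1)) * dt
  mk <- gait_marker_positions(p, t)
  segs <- model$segments
  M <- model$total_mass
  nn <- length(t)
  ii <- 2:(nn - 1)  # interior frames: k = 0 .. N, exactly n_strides periods
  cdiff <- function(z) (z[3:nn] - z[1:(nn - 2)]) / (2 * dt)
  com_num <- matrix(0, nn, 2)
  seg <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    P <- mk[[segs$proximal_marker[i]]]
    D <- mk[[segs$distal_marker[i]]]
    C <- P + segs$com_fraction[i] * (D - P)
    ang <- unwrap_angle(atan2(D[, 2] - P[, 2], D[, 1] - P[, 1]))
    len <- sqrt(rowSums((D - P)^2))
    seg[[i]] <- list(
      m = segs$mass_fraction[i] * M,
      K = segs$gyration_fraction[i] * mean(len[ii]),
      v = cbind(cdiff(C[, 1]), cdiff(C[, 2])),
      omega = cdiff(ang))
    com_num <- com_num + segs$mass_fraction[i] * M * C
  }
  com <- com_num / M
  V <- cbind(cdiff(com[, 1]), cdiff(com[, 2]))
  spi <- function(E) sum(pmax(diff(E), 0))
  groups <- unique(segs$group)
  per_limb <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    Eg <- 0
    for (i in which(segs$group == g)) {
      s <- seg[[i]]
      vr <- s$v - V
      Eg <- Eg + 0.5 * s$m * (vr[, 1]^2 + vr[, 2]^2) +
        0.5 * s$m * s$K^2 * s$omega^2
    }
    per_limb[g] <- spi(Eg)
  }
  W_int <- sum(per_limb)
  Ecm <- M * model$g * com[ii, 2] +
    0.5 * M * (V[, 1] + p$belt_speed)^2 + 0.5 * M * V[, 2]^2
  W_ext <- spi(Ecm)
  W_tot <- W_int + W_ext
  distance <- p$belt_speed * n_strides * Tp
  normalized <- NULL
  if (distance > 0)
    normalized <- data.frame(
      b = b_values,
      W_int = W_int / (M^b_values * distance),
      W_ext = W_ext / (M^b_values * distance),
      W_tot = W_tot / (M^b_values * distance))
  list(W_int_abs = W_int, W_ext_abs = W_ext, W_tot_abs = W_tot,
       per_limb = per_limb, distance = distance, normalized = normalized,
       n_strides = n_strides, grid_rate = grid_rate)
}

#' Generate a cohort obeying an allometric power law
#'
#' Body masses are drawn from a normal distribution truncated below at
#' 40 kg; absolute maximal oxygen uptake follows
#' `VO2max = a * M^b * 10^e` with `e ~ N(0, log_noise_sd)` (multiplicative
#' log-normal noise, the error model under which log-log least squares is
#' the natural estimator).  Defaults emulate a cohort of recreational
#' runners: n = 14, mass 70 +/- 10.2 kg, and `a` chosen so that a 70-kg
#' runner has an absolute VO2max of about 3640 ml min^-1 (52 ml kg^-1
#' min^-1).
#'
#' @param n Number of subjects (>= 3).
#' @param mass_mean,mass_sd Body-mass distribution, kg.
#' @param a,b Allometric coefficient and exponent.
#' @param log_noise_sd Standard deviation of the base-10 log noise.
#' @param seed Integer seed.
#' @return Data frame with `subject_id`, `body_mass_kg`,
#'   `vo2max_abs_ml_min`.
#' @export
generate_vo2_cohort <- function(n = 14, mass_mean = 70, mass_sd = 10.2,
                                a = 454, b = 0.49, log_noise_sd = 0.03,
                                seed = 1) {
  if (n < 3) stop("cohort needs at least 3 subjects")
  if (a <= 0 || mass_mean <= 40) stop("invalid cohort parameters")
  set.seed(seed)
  mass <- stats::rnorm(n, mass_mean, mass_sd)
  while (any(mass <= 40))
    mass[mass <= 40] <- stats::rnorm(sum(mass <= 40), mass_mean, mass_sd)
  eps <- stats::rnorm(n, 0, log_noise_sd)
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             body_mass_kg = mass,
             vo2max_abs_ml_min = a * mass^b * 10^eps,
             stringsAsFactors = FALSE)
}

#' Generate a runner cohort with an exact work-performance correlation
#'
#' Per-subject mechanical works (`b = 1`, J kg^-1 m^-1) are drawn around
#' study-like means, and the 10 000-m performance time is built as
#' `performance = slope * W_ext + intercept + noise` with the noise
#' orthogonalised against `W_ext` (Gram-Schmidt via regression residuals)
#' and scaled so that the *sample* Pearson correlation between `W_ext` and
#' performance equals `target_r` exactly, not merely in expectation.
#'
#' @param n Number of subjects (>= 3).
#' @param target_r Requested sample correlation, in `[-1, 1]`.
#' @param mass_mean,mass_sd Body-mass distribution, kg (truncated > 40).
#' @param wint_mean,wint_sd,wext_mean,wext_sd Work distributions at `b = 1`,
#'   J kg^-1 m^-1.
#' @param wint_wext_cor Latent correlation between the two work components.
#' @param slope,intercept Performance prediction line (seconds per unit
#'   work, seconds).
#' @param seed Integer seed.
#' @return Data frame with `subject_id`, `body_mass_kg`, `w_int`, `w_ext`,
#'   `w_tot` (J kg^-1 m^-1) and `performance_s`.
#' @export
generate_runner_cohort <- function(n = 14, target_r = 0.80,
                                   mass_mean = 70, mass_sd = 10.2,
                                   wint_mean = 0.63, wint_sd = 0.13,
                                   wext_mean = 1.22, wext_sd = 0.13,
                                   wint_wext_cor = 0.5,
                                   slope = 2649, intercept = -621.28,
                                   seed = 1) {
  if (n < 3) stop("cohort needs at least 3 subjects")
  if (!is.finite(target_r) || abs(target_r) > 1)
    stop("target_r must lie in [-1, 1]")
  set.seed(seed)
  mass <- stats::rnorm(n, mass_mean, mass_sd)
  while (any(mass <= 40))
    mass[mass <= 40] <- stats::rnorm(sum(mass <= 40), mass_mean, mass_sd)
  draw_pos <- function(mean, sd, z) {
    v <- mean + sd * z
    while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mean, sd)
    v
  }
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  w_ext <- draw_pos(wext_mean, wext_sd, z1)
  w_int <- draw_pos(wint_mean, wint_sd,
                    wint_wext_cor * z1 + sqrt(1 - wint_wext_cor^2) * z2)
  s <- if (sign(slope) == sign(target_r) || target_r == 0) slope else -slope
  eps <- stats::rnorm(n)
  eps_perp <- stats::residuals(stats::lm(eps ~ w_ext))
  if (target_r == 0) {
    perf <- intercept + s * mean(w_ext) +
      eps_perp / stats::sd(eps_perp) * abs(s) * stats::sd(w_ext)
  } else if (abs(target_r) == 1) {
    perf <- s * w_ext + intercept
  } else {
    sd_noise <- abs(s) * stats::sd(w_ext) * sqrt(1 / target_r^2 - 1)
    perf <- s * w_ext + intercept + eps_perp / stats::sd(eps_perp) * sd_noise
  }
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             body_mass_kg = mass, w_int = w_int, w_ext = w_ext,
             w_tot = w_int + w_ext, performance_s = perf,
             stringsAsFactors = FALSE)
}
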