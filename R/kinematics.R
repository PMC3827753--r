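#' Marker trajectory container
#'
#' Bundles time-indexed 2-D sagittal marker positions with their sampling
#' metadata.  Coordinates are metres: `x` antero-posterior (positive in the
#' direction of progression), `y` vertical (positive up).  On a treadmill the
#' positions are recorded in the camera (lab) frame; `belt_speed` is used
#' later to express forward velocities in the belt frame.
#'
#' @param markers Named list of numeric matrices, one per marker, each with
#'   two columns (`x`, `y`) and one row per frame.  All markers must share
#'   the same frame count and contain no missing values.
#' @param sample_rate Sampling rate in Hz.
#' @param belt_speed Treadmill belt speed in m s^-1 (0 for overground).
#' @return An object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(markers, sample_rate, belt_speed = 0) {
  if (!is.list(markers) || is.null(names(markers)) || any(names(markers) == ""))
    stop("markers must be a named list of n x 2 matrices")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number (Hz)")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("each marker needs exactly two columns (x, y)")
    colnames(m) <- c("x", "y")
    storage.mode(m) <- "double"
    m
  })
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1)
    stop("all markers must have the same number of frames")
  if (any(vapply(markers, anyNA, logical(1))))
    stop("marker trajectories contain missing values after loading")
  structure(
    list(markers = markers, sample_rate = sample_rate,
         belt_speed = belt_speed, n_frames = unname(nf[1]),
         duration = unname(nf[1]) / sample_rate),
    class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf(
    "Marker trajectories: %d markers, %d frames at %g Hz (%.2f s), belt %.2f m s^-1\n",
    length(x$markers), x$n_frames, x$sample_rate, x$duration, x$belt_speed))
  invisible(x)
}

get_marker <- function(traj, name) {
  m <- traj$markers[[name]]
  if (is.null(m)) stop("marker not found in trajectories: ", name)
  m
}

#' Load marker trajectories from a delimited text file
#'
#' The file must have a header `frame, <marker>_x, <marker>_y, ...` and one
#' row per frame, coordinates in metres.  Tab-, comma- and
#' semicolon-delimited files are detected automatically.  Missing samples
#' (`NA`) spanning at most `max_gap` consecutive frames are filled by linear
#' interpolation with a warning; longer gaps abort the load with the frame
#' index of the offending gap.
#'
#' @param path Path to the marker file.
#' @param sample_rate Sampling rate in Hz.
#' @param belt_speed Treadmill belt speed in m s^-1.
#' @param max_gap Longest gap (frames) that will be interpolated (default 5).
#' @return A [marker_trajectories()] object.
#' @export
load_markers <- function(path, sample_rate, belt_speed = 0, max_gap = 5) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  cols <- names(tab)
  xs <- grep("_x$", cols, value = TRUE)
  base <- sub("_x$", "", xs)
  ys <- paste0(base, "_y")
  if (length(base) == 0 || !all(ys %in% cols))
    stop("marker file needs paired <marker>_x / <marker>_y columns")
  markers <- list()
  for (i in seq_along(base)) {
    m <- cbind(x = as.numeric(tab[[xs[i]]]), y = as.numeric(tab[[ys[i]]]))
    m <- fill_gaps(m, base[i], max_gap)
    markers[[base[i]]] <- m
  }
  marker_trajectories(markers, sample_rate, belt_speed)
}

# linear interpolation of NA runs up to max_gap frames; hard error otherwise
fill_gaps <- function(m, name, max_gap) {
  for (j in 1:2) {
    v <- m[, j]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    bad <- which(r$values & (r$lengths > max_gap |
                             starts == 1 | ends == length(v)))
    if (length(bad) > 0)
      stop(sprintf(
        "marker '%s': gap of %d frame(s) starting at frame %d exceeds max_gap = %d (or touches the record edge)",
        name, r$lengths[bad[1]], starts[bad[1]], max_gap))
    n_gaps <- sum(r$values)
    m[, j] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                            xout = seq_along(v))$y
    warning(sprintf("marker '%s': interpolated %d gap(s) of <= %d frame(s)",
                    name, n_gaps, max_gap))
  }
  m
}

#' Write marker trajectories to a delimited text file
#'
#' Inverse of [load_markers()]; useful for exporting synthetic gaits in the
#' format the pipeline reads.
#'
#' @param traj A [marker_trajectories()] object.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_markers <- function(traj, path, sep = "\t") {
  stopifnot(inherits(traj, "marker_trajectories"))
  out <- data.frame(frame = seq_len(traj$n_frames) - 1L)
  for (nm in names(traj$markers)) {
    out[[paste0(nm, "_x")]] <- traj$markers[[nm]][, 1]
    out[[paste0(nm, "_y")]] <- traj$markers[[nm]][, 2]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-lag low-pass Butterworth filter
#'
#' Second-order Butterworth applied forward and backward (zero phase lag,
#' effective fourth order), with odd reflection padding at both ends to
#' suppress edge transients.  Zero-lag filtering is obligatory before
#' numerical differentiation, since phase distortion would bias velocities.
#'
#' @param x Numeric series.
#' @param cutoff Cut-off frequency in Hz; must satisfy
#'   `0 < cutoff < sample_rate / 2`.
#' @param sample_rate Sampling rate in Hz.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff, sample_rate) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff >= sample_rate / 2)
    stop("cutoff must satisfy 0 < cutoff < sample_rate / 2")
  n <- length(x)
  bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
  pad <- min(n - 1, ceiling(3 * sample_rate / cutoff))
  if (pad < 1) return(x)
  # demean so the filter's zero initial state sees only the fluctuation
  # (a constant series passes through exactly), and reflect oddly at both
  # ends so level and slope are continuous across the padding
  mu <- mean(x)
  x0 <- x - mu
  left <- 2 * x0[1] - x0[(pad + 1):2]
  right <- 2 * x0[n] - x0[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(left, x0, right))
  mu + y[(pad + 1):(pad + n)]
}

#' Automatic cut-off frequency selection by residual analysis
#'
#' Chooses a low-pass cut-off per marker by Winter's residual analysis: the
#' RMS residual between the raw and filtered series is computed over a grid
#' of candidate cut-offs, a straight line is fitted to the high-frequency
#' (noise-dominated) tail of the residual curve, and the chosen cut-off is
#' the lowest candidate whose residual falls to the extrapolated noise
#' intercept (within 1% of the series' standard deviation).  The result is
#' clamped to `clamp` (default 8-11 Hz, the range used for running
#' kinematics captured at 240 Hz).
#'
#' @param traj A [marker_trajectories()] object (duration at least 1 s).
#' @param clamp Length-2 numeric: allowed cut-off range in Hz.
#' @return Named numeric vector: one cut-off (Hz) per marker (the larger of
#'   the x- and y-coordinate selections, so neither coordinate is
#'   over-smoothed).
#' @export
auto_cutoff <- function(traj, clamp = c(8, 11)) {
  stopifnot(inherits(traj, "marker_trajectories"))
  fs <- traj$sample_rate
  if (fs < 2 * max(clamp))
    stop(sprintf(
      "sample_rate %g Hz violates the Nyquist limit for a %g Hz cut-off",
      fs, max(clamp)))
  if (traj$duration < 1)
    stop("residual analysis needs at least 1 s of data")
  vapply(traj$markers, function(m) {
    fc <- max(residual_cutoff(m[, 1], fs), residual_cutoff(m[, 2], fs))
    min(max(fc, clamp[1]), clamp[2])
  }, numeric(1))
}

# Winter residual analysis on a single series; returns the unclamped choice
residual_cutoff <- function(x, fs) {
  cands <- seq(1, min(20, 0.9 * fs / 2), by = 0.5)
  res <- vapply(cands, function(fc) {
    sqrt(mean((x - lowpass_filter(x, fc, fs))^2))
  }, numeric(1))
  tail_idx <- cands >= cands[1] + 0.75 * diff(range(cands))
  fit <- stats::lm(res[tail_idx] ~ cands[tail_idx])
  noise0 <- max(unname(stats::coef(fit)[1]), 0)
  tol <- 0.01 * stats::sd(x)
  if (!is.finite(tol)) tol <- 0
  hit <- which(res <= noise0 + tol)
  if (length(hit) == 0) cands[length(cands)] else cands[hit[1]]
}

#' Filter every marker of a trajectory set
#'
#' Applies [lowpass_filter()] to both coordinates of every marker, with
#' per-marker cut-offs from [auto_cutoff()] unless given explicitly.
#'
#' @param traj A [marker_trajectories()] object.
#' @param cutoffs Optional: a single cut-off (Hz) for all markers, or a named
#'   vector with one entry per marker.
#' @return A filtered [marker_trajectories()] object with attribute
#'   `"cutoffs"` recording the cut-off used per marker.
#' @export
filter_trajectories <- function(traj, cutoffs = NULL) {
  stopifnot(inherits(traj, "marker_trajectories"))
  if (is.null(cutoffs)) cutoffs <- auto_cutoff(traj)
  if (length(cutoffs) == 1 && is.null(names(cutoffs)))
    cutoffs <- stats::setNames(rep(cutoffs, length(traj$markers)),
                               names(traj$markers))
  out <- traj
  for (nm in names(traj$markers)) {
    fc <- cutoffs[[nm]]
    if (is.null(fc) || is.na(fc)) stop("no cutoff provided for marker ", nm)
    out$markers[[nm]][, 1] <- lowpass_filter(traj$markers[[nm]][, 1], fc,
                                             traj$sample_rate)
    out$markers[[nm]][, 2] <- lowpass_filter(traj$markers[[nm]][, 2], fc,
                                             traj$sample_rate)
  }
  attr(out, "cutoffs") <- cutoffs[names(traj$markers)]
  out
}

#' Numerical differentiation
#'
#' Central differences in the interior, one-sided differences at the ends;
#' exact for linear series.
#'
#' @param x Numeric series of length at least 3.
#' @param sample_rate Sampling rate in Hz.
#' @return The derivative series, same length as `x`.
#' @export
differentiate <- function(x, sample_rate) {
  n <- length(x)
  if (n < 3) stop("differentiate needs a series of length >= 3")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * sample_rate / 2
  d[1] <- (x[2] - x[1]) * sample_rate
  d[n] <- (x[n] - x[n - 1]) * sample_rate
  d
}

unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  a[1] + c(0, cumsum(d))
}

#' Stride window
#'
#' A contiguous analysis window spanning an integral number of strides.
#' Boundary frames are 1-based and inclusive; energy increments are summed
#' over `start:end`, so the window covers `end - start` inter-frame steps.
#'
#' @param start,end First and last boundary frame (1-based, `end > start`).
#' @param n_strides Number of complete strides inside the window.
#' @param sample_rate Sampling rate in Hz (used for durations).
#' @param boundaries Optional vector of all stride boundary frames.
#' @return An object of class `stride_window`.
#' @export
stride_window <- function(start, end, n_strides, sample_rate,
                          boundaries = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("stride window must have end > start")
  if (n_strides < 1) stop("n_strides must be >= 1")
  if (is.null(boundaries)) boundaries <- c(start, end)
  if (any(diff(boundaries) <= 0))
    stop("stride boundaries must be strictly increasing")
  structure(
    list(start = start, end = end, n_strides = as.integer(n_strides),
         boundaries = as.integer(boundaries), sample_rate = sample_rate,
         duration = (end - start) / sample_rate,
         stride_period = (end - start) / n_strides / sample_rate),
    class = "stride_window")
}

#' @export
print.stride_window <- function(x, ...) {
  cat(sprintf(
    "Stride window: %d stride(s), frames [%d, %d], %.3f s (stride period %.4f s)\n",
    x$n_strides, x$start, x$end, x$duration, x$stride_period))
  invisible(x)
}

#' Detect strides from a foot marker's vertical trajectory
#'
#' Stride boundaries are successive minima of the vertical position of a
#' foot marker of one side (default the left heel).  The stride period is
#' first estimated from the dominant peak of the autocorrelation of the
#' (low-pass filtered, mean-removed) series within a physiological band;
#' boundaries are then placed at the deepest minimum inside each
#' period-length search window.  The last `n_strides` complete strides are
#' returned.
#'
#' @param traj A [marker_trajectories()] object.
#' @param n_strides Number of complete strides to keep (default 5).
#' @param marker Marker whose vertical coordinate is segmented.
#' @param period_range Plausible stride period range in seconds.
#' @param min_autocorr Minimum autocorrelation at the period lag; below this
#'   the record is considered non-periodic and an error is raised.
#' @return A [stride_window()] object.
#' @export
detect_strides <- function(traj, n_strides = 5, marker = "heel_L",
                           period_range = c(0.3, 2), min_autocorr = 0.3) {
  stopifnot(inherits(traj, "marker_trajectories"))
  fs <- traj$sample_rate
  y <- get_marker(traj, marker)[, 2]
  y <- lowpass_filter(y, min(8, 0.45 * fs), fs)
  y <- y - mean(y)
  n <- length(y)
  lag_min <- max(2L, round(period_range[1] * fs))
  lag_max <- min(n - 2L, round(period_range[2] * fs))
  if (lag_max <= lag_min)
    stop("record too short for stride detection in the given period range")
  ac <- stats::acf(y, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- lag_min:lag_max
  acl <- ac[lags + 1]
  # local maxima of the autocorrelation within the band
  is_peak <- c(FALSE, diff(sign(diff(acl))) < 0, FALSE)
  if (!any(is_peak))
    stop("no periodic structure found in marker '", marker, "'")
  peak_lag <- lags[is_peak][which.max(acl[is_peak])]
  if (max(acl[is_peak]) < min_autocorr)
    stop(sprintf(
      "marker '%s' is not periodic enough for stride detection (max autocorrelation %.2f)",
      marker, max(acl[is_peak])))
  period <- peak_lag
  # anchor at the global minimum, then march outward one period at a time,
  # taking the deepest sample inside a +/- period/4 search window
  half_win <- max(1L, round(period / 4))
  anchor <- which.min(y)
  centres <- anchor + period *
    (floor((1 - anchor) / period):floor((n - anchor) / period))
  boundaries <- integer(0)
  for (ctr in centres) {
    lo <- ctr - half_win; hi <- ctr + half_win
    if (lo < 1 || hi > n) next
    boundaries <- c(boundaries, lo - 1L + which.min(y[lo:hi]))
  }
  boundaries <- unique(boundaries)
  found <- length(boundaries) - 1L
  if (found < n_strides)
    stop(sprintf("found %d complete stride(s), but %d requested",
                 max(found, 0L), n_strides))
  keep <- boundaries[(found + 1 - n_strides):(found + 1)]
  stride_window(keep[1], keep[length(keep)], n_strides, fs,
                boundaries = keep)
}

#' Synthesise the contralateral side by a half-stride time shift
#'
#' The unfilmed right side is estimated from the filmed left side under the
#' assumption of a symmetric periodic gait: each left-side marker (`*_L`)
#' is expressed relative to the pelvis (`anchor` marker), that relative
#' trajectory is time-shifted by half a stride period, and the result is
#' re-attached to the pelvis at the current time.  Anchoring the shift to
#' the pelvis keeps whole-body motion (the centre-of-mass oscillation,
#' which is common to both sides) at its actual phase and delays only the
#' reciprocal limb motion; a rigidly moving body therefore mirrors to a
#' rigidly moving body.  With `anchor = NULL` the markers are time-shifted
#' wholesale instead.  Shifted samples are taken by linear interpolation;
#' target times outside the record are wrapped by whole stride periods, so
#' the record must span at least one stride.
#'
#' @param traj A [marker_trajectories()] object containing `*_L` markers.
#' @param stride_period Stride period in seconds (e.g. from
#'   [detect_strides()]).
#' @param anchor Marker the shift is taken relative to (default `"hip"`),
#'   or `NULL` for a plain time shift.
#' @return The trajectory set with `*_R` markers added.
#' @export
mirror_contralateral <- function(traj, stride_period, anchor = "hip") {
  stopifnot(inherits(traj, "marker_trajectories"))
  if (!is.numeric(stride_period) || stride_period <= 0)
    stop("stride_period must be positive")
  if (traj$duration < stride_period)
    stop("record shorter than one stride period; cannot mirror")
  fs <- traj$sample_rate
  t <- (seq_len(traj$n_frames) - 1) / fs
  tgt <- t - stride_period / 2
  # wrap into the recorded range by whole periods (periodicity assumption)
  below <- tgt < t[1]
  tgt[below] <- tgt[below] +
    stride_period * ceiling((t[1] - tgt[below]) / stride_period)
  above <- tgt > t[length(t)]
  tgt[above] <- tgt[above] -
    stride_period * ceiling((tgt[above] - t[length(t)]) / stride_period)
  shift <- function(m) cbind(x = stats::approx(t, m[, 1], xout = tgt)$y,
                             y = stats::approx(t, m[, 2], xout = tgt)$y)
  ref <- if (is.null(anchor)) NULL else get_marker(traj, anchor)
  out <- traj
  for (nm in grep("_L$", names(traj$markers), value = TRUE)) {
    m <- traj$markers[[nm]]
    out$markers[[sub("_L$", "_R", nm)]] <- if (is.null(ref)) {
      shift(m)
    } else {
      ref + shift(m - ref)
    }
  }
  out$markers <- lapply(out$markers, function(m) {
    colnames(m) <- c("x", "y"); m
  })
  out
}

#' Segment and whole-body centre-of-mass kinematics
#'
#' For every segment of the model: centre-of-mass position
#' (`proximal + com_fraction * (distal - proximal)`), linear velocity by
#' numerical differentiation, angular velocity as the derivative of the
#' unwrapped segment orientation, and radius of gyration
#' `K = gyration_fraction * mean segment length` over the analysis window.
#' The body centre of mass is the mass-weighted mean of the segment centres
#' of mass; segment velocities relative to it therefore satisfy
#' `sum_i m_i v_rel,i = 0` at every frame.  The antero-posterior
#' centre-of-mass velocity is also expressed in the belt frame
#' (lab velocity + belt speed).
#'
#' @param traj A filtered [marker_trajectories()] object containing every
#'   marker the model references (both sides).
#' @param model A [build_body_model()] object.
#' @param window Optional [stride_window()]; used for the mean segment
#'   length defining `K` (the kinematic series always cover all frames).
#' @return An object of class `segment_kinematics`: per-segment list
#'   (`mass`, `K`, `com`, `v`, `v_rel`, `omega`) plus `com` (body
#'   centre-of-mass position `pos`, height `h`, lab-frame velocity `v_lab`,
#'   belt-frame velocity `v_belt`).
#' @export
compute_segment_kinematics <- function(traj, model, window = NULL) {
  stopifnot(inherits(traj, "marker_trajectories"),
            inherits(model, "body_model"))
  fs <- traj$sample_rate
  n <- traj$n_frames
  widx <- if (is.null(window)) seq_len(n) else window$start:window$end
  segs <- model$segments
  M <- model$total_mass
  seg_out <- vector("list", nrow(segs))
  names(seg_out) <- segs$name
  com_num <- matrix(0, n, 2)
  for (i in seq_len(nrow(segs))) {
    P <- get_marker(traj, segs$proximal_marker[i])
    D <- get_marker(traj, segs$distal_marker[i])
    C <- P + segs$com_fraction[i] * (D - P)
    len <- sqrt(rowSums((D - P)^2))
    ang <- unwrap_angle(atan2(D[, 2] - P[, 2], D[, 1] - P[, 1]))
    m <- segs$mass_fraction[i] * M
    seg_out[[i]] <- list(
      name = segs$name[i], mass = m,
      K = segs$gyration_fraction[i] * mean(len[widx]),
      com = C,
      v = cbind(differentiate(C[, 1], fs), differentiate(C[, 2], fs)),
      omega = differentiate(ang, fs))
    com_num <- com_num + m * C
  }
  com_pos <- com_num / M
  V <- cbind(differentiate(com_pos[, 1], fs), differentiate(com_pos[, 2], fs))
  for (i in seq_along(seg_out))
    seg_out[[i]]$v_rel <- seg_out[[i]]$v - V
  structure(
    list(sample_rate = fs, n_frames = n, segments = seg_out,
         com = list(pos = com_pos, h = com_pos[, 2], v_lab = V,
                    v_belt = cbind(V[, 1] + traj$belt_speed, V[, 2])),
         total_mass = M, g = model$g, belt_speed = traj$belt_speed,
         window = window),
    class = "segment_kinematics")
}
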