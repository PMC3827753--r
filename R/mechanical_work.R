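#' Kinetic energy of a segment relative to the body centre of mass
#'
#' `KE_r = 1/2 m (v_ap_r^2 + v_v_r^2) + 1/2 m K^2 omega^2`: translational
#' kinetic energy of the segment centre of mass relative to the body centre
#' of mass, plus rotational kinetic energy about the segment centre of mass.
#'
#' @param m Segment mass, kg (positive).
#' @param v_ap_r,v_v_r Antero-posterior and vertical components of the
#'   segment centre-of-mass velocity relative to the body centre of mass,
#'   m s^-1.  Vectorised over frames.
#' @param K Segment radius of gyration, m (non-negative).
#' @param omega Segment angular velocity, rad s^-1.
#' @return Kinetic energy in J (same length as the velocity inputs).
#' @export
ke_relative <- function(m, v_ap_r, v_v_r, K, omega) {
  if (!is.numeric(m) || any(m <= 0)) stop("segment mass must be positive")
  if (any(K < 0)) stop("radius of gyration must be non-negative")
  0.5 * m * (v_ap_r^2 + v_v_r^2) + 0.5 * m * K^2 * omega^2
}

#' Sum of positive increments of an energy curve
#'
#' The positive-work convention: only positive frame-to-frame increments of
#' the energy curve count; negative increments (negative work) are
#' discarded.  Increments are summed over the stride window, i.e. over the
#' `end - start` steps between frames `start` and `end`.
#'
#' @param series Energy series in J.
#' @param window A [stride_window()], or `NULL` for the whole series.
#' @return Positive work in J.
#' @export
positive_increments <- function(series, window = NULL) {
  idx <- if (is.null(window)) seq_along(series) else window$start:window$end
  if (length(idx) < 2) stop("window must span at least two frames")
  if (idx[1] < 1 || idx[length(idx)] > length(series))
    stop("window exceeds the series")
  d <- diff(series[idx])
  sum(pmax(d, 0))
}

#' Per-segment relative kinetic energy series
#'
#' @param kin A [compute_segment_kinematics()] object.
#' @return Numeric matrix, frames x segments, of `KE_r` in J.
#' @export
segment_energies <- function(kin) {
  stopifnot(inherits(kin, "segment_kinematics"))
  E <- vapply(kin$segments, function(s) {
    ke_relative(s$mass, s$v_rel[, 1], s$v_rel[, 2], s$K, s$omega)
  }, numeric(kin$n_frames))
  colnames(E) <- names(kin$segments)
  E
}

#' Per-limb-group summed kinetic energy series
#'
#' Segment energies within the same limb group are summed *before* taking
#' positive increments: this is the assumption that mechanical energy
#' transfers freely between segments of the same limb, but not between
#' limbs or between a limb and the trunk.
#'
#' @param kin A [compute_segment_kinematics()] object.
#' @param model The [build_body_model()] the kinematics were computed with.
#' @return Numeric matrix, frames x limb groups.
#' @export
limb_energies <- function(kin, model) {
  E <- segment_energies(kin)
  groups <- model$segments$group[match(colnames(E), model$segments$name)]
  out <- vapply(unique(groups), function(g) {
    rowSums(E[, groups == g, drop = FALSE])
  }, numeric(nrow(E)))
  colnames(out) <- unique(groups)
  out
}

#' Internal mechanical work
#'
#' For each of the five limb groups (left/right upper limb, left/right
#' lower limb, head-trunk) the member segments' relative kinetic energies
#' are summed first, and the positive increments of each group curve are
#' then accumulated over the stride window; `W_int` is the sum over groups.
#' The order (sum, then increment) encodes the within-limb energy-transfer
#' assumption and must not be swapped.
#'
#' @param kin A [compute_segment_kinematics()] object.
#' @param model The matching [build_body_model()].
#' @param window A [stride_window()].
#' @return List with `total` (J) and `per_limb` (named numeric, J).
#' @export
internal_work <- function(kin, model, window) {
  EL <- limb_energies(kin, model)
  per_limb <- apply(EL, 2, positive_increments, window = window)
  list(total = sum(per_limb), per_limb = per_limb)
}

#' Mechanical energy of the body centre of mass
#'
#' `E_CM = M g h + 1/2 M V_ap^2 + 1/2 M V_v^2`, with the antero-posterior
#' velocity expressed in the belt frame so that the forward kinetic energy
#' reflects the progression speed.
#'
#' @param kin A [compute_segment_kinematics()] object.
#' @return Data frame with columns `PE`, `KE_ap`, `KE_v`, `E_CM` (J per
#'   frame).
#' @export
com_energy <- function(kin) {
  stopifnot(inherits(kin, "segment_kinematics"))
  M <- kin$total_mass
  PE <- M * kin$g * kin$com$h
  KE_ap <- 0.5 * M * kin$com$v_belt[, 1]^2
  KE_v <- 0.5 * M * kin$com$v_belt[, 2]^2
  data.frame(PE = PE, KE_ap = KE_ap, KE_v = KE_v, E_CM = PE + KE_ap + KE_v)
}

#' External mechanical work
#'
#' Positive increments of the centre-of-mass energy `E_CM` over the stride
#' window.  Because potential and kinetic terms are summed before
#' incrementing, energy exchange between them (pendular transfer) is
#' implicitly allowed.
#'
#' @param com_E The [com_energy()] data frame (or any object with an
#'   `E_CM` column).
#' @param window A [stride_window()].
#' @return `W_ext` in J.
#' @export
external_work <- function(com_E, window) {
  positive_increments(com_E$E_CM, window)
}

#' Total mechanical work
#'
#' Arithmetic sum of internal and external work, justified by the Koenig
#' decomposition of the kinetic energy of a multilink system.
#'
#' @param W_int,W_ext Non-negative works (any consistent unit).
#' @return `W_int + W_ext`.
#' @export
total_work <- function(W_int, W_ext) {
  if (any(W_int < 0) || any(W_ext < 0))
    stop("works must be non-negative under the positive-work convention")
  W_int + W_ext
}

#' Koenig decomposition residual
#'
#' Checks, frame by frame, the identity behind the `W_int`/`W_ext`
#' partition: the total translational kinetic energy of the segments equals
#' the kinetic energy of the whole-body centre of mass plus the kinetic
#' energy of the segments relative to it,
#' `sum 1/2 m_i |v_i|^2 = 1/2 M |V|^2 + sum 1/2 m_i |v_rel,i|^2`
#' (lab frame, translational terms).  The residual should vanish to
#' numerical precision whenever the body centre of mass is the mass-weighted
#' mean of the segment centres of mass.
#'
#' @param kin A [compute_segment_kinematics()] object.
#' @return Data frame with per-frame `total_ke`, `residual` and `relative`
#'   (residual over total, 0 where the total is 0).
#' @export
koenig_residual <- function(kin) {
  stopifnot(inherits(kin, "segment_kinematics"))
  n <- kin$n_frames
  ke_abs <- ke_rel <- numeric(n)
  for (s in kin$segments) {
    ke_abs <- ke_abs + 0.5 * s$mass * rowSums(s$v^2)
    ke_rel <- ke_rel + 0.5 * s$mass * rowSums(s$v_rel^2)
  }
  ke_com <- 0.5 * kin$total_mass * rowSums(kin$com$v_lab^2)
  residual <- ke_abs - (ke_com + ke_rel)
  data.frame(total_ke = ke_abs, residual = residual,
             relative = ifelse(ke_abs > 0, residual / ke_abs, 0))
}

#' Normalise work to J kg^-b m^-1
#'
#' Expresses an absolute work over a window in the units of the energy cost
#' of running: `W / (M^b * distance)`, where `b` is the allometric exponent
#' (1 for simple mass-specific work).
#'
#' @param W_abs Absolute work over the window, J.
#' @param M Body mass, kg (positive).
#' @param b Allometric exponent (dimensionless).
#' @param distance Distance travelled over the window, m (positive).
#' @return Work in J kg^-b m^-1.
#' @export
normalize_work <- function(W_abs, M, b, distance) {
  if (any(M <= 0)) stop("body mass must be positive")
  if (any(distance <= 0)) stop("distance must be positive")
  W_abs / (M^b * distance)
}

#' Compute internal, external and total mechanical work from markers
#'
#' End-to-end driver for one trial: low-pass filters the marker
#' trajectories (automatic per-marker cut-off), segments strides on the
#' heel marker, synthesises the contralateral side by a half-stride shift
#' when right-side markers are absent, computes segment and centre-of-mass
#' kinematics, and accumulates positive energy increments over the stride
#' window.  Works are reported in absolute J over the window and normalised
#' to J kg^-b m^-1 for each requested exponent, with the distance taken as
#' `belt_speed * window duration` on a treadmill (centre-of-mass horizontal
#' displacement overground).
#'
#' @param traj A raw [marker_trajectories()] object (left-side markers, or
#'   both sides).
#' @param model A [build_body_model()] object.
#' @param n_strides Number of strides to analyse (default 5).
#' @param b_values Allometric exponents for normalisation.
#' @param window Optional [stride_window()] to bypass stride detection
#'   (needed for degenerate, non-periodic inputs such as a static pose).
#' @param cutoffs Optional fixed filter cut-off(s), see
#'   [filter_trajectories()].
#' @param stride_marker Marker used for stride detection.
#' @return An object of class `work_result`: absolute works (`W_int_abs`,
#'   `W_ext_abs`, `W_tot_abs`, `per_limb`), the `normalized` table (one row
#'   per `b`), window metadata and the filter cut-offs used.
#' @export
compute_work <- function(traj, model, n_strides = 5,
                         b_values = c(1, 0.75), window = NULL,
                         cutoffs = NULL, stride_marker = "heel_L") {
  stopifnot(inherits(traj, "marker_trajectories"),
            inherits(model, "body_model"))
  if (length(b_values) < 1) stop("b_values must be non-empty")
  ftraj <- filter_trajectories(traj, cutoffs)
  if (is.null(window)) {
    window <- detect_strides(ftraj, n_strides = n_strides,
                             marker = stride_marker)
  }
  need_r <- setdiff(model_markers(model), names(ftraj$markers))
  if (length(need_r) > 0) {
    if (!all(grepl("_R$", need_r)))
      stop("missing non-mirrorable markers: ",
           paste(setdiff(need_r, grep("_R$", need_r, value = TRUE)),
                 collapse = ", "))
    ftraj <- mirror_contralateral(ftraj, window$stride_period)
  }
  kin <- compute_segment_kinematics(ftraj, model, window)
  wi <- internal_work(kin, model, window)
  we <- external_work(com_energy(kin), window)
  wt <- total_work(wi$total, we)
  distance <- if (traj$belt_speed > 0) {
    traj$belt_speed * window$duration
  } else {
    abs(kin$com$pos[window$end, 1] - kin$com$pos[window$start, 1])
  }
  normalized <- NULL
  if (distance > 0) {
    normalized <- data.frame(
      b = b_values,
      W_int = vapply(b_values, function(b)
        normalize_work(wi$total, model$total_mass, b, distance), numeric(1)),
      W_ext = vapply(b_values, function(b)
        normalize_work(we, model$total_mass, b, distance), numeric(1)),
      W_tot = vapply(b_values, function(b)
        normalize_work(wt, model$total_mass, b, distance), numeric(1)))
  }
  structure(
    list(W_int_abs = wi$total, W_ext_abs = we, W_tot_abs = wt,
         per_limb = wi$per_limb, distance = distance,
         M = model$total_mass, n_strides = window$n_strides,
         duration = window$duration, normalized = normalized,
         window = window, cutoffs = attr(ftraj, "cutoffs")),
    class = "work_result")
}

#' @export
print.work_result <- function(x, ...) {
  cat(sprintf(
    "Mechanical work over %d stride(s) (%.3f s, %.2f m, M = %.1f kg)\n",
    x$n_strides, x$duration, x$distance, x$M))
  cat(sprintf("  W_int = %.2f J, W_ext = %.2f J, W_tot = %.2f J\n",
              x$W_int_abs, x$W_ext_abs, x$W_tot_abs))
  if (!is.null(x$normalized)) {
    for (i in seq_len(nrow(x$normalized)))
      cat(sprintf(
        "  b = %-5.3g: W_int %.3f, W_ext %.3f, W_tot %.3f J kg^-b m^-1\n",
        x$normalized$b[i], x$normalized$W_int[i],
        x$normalized$W_ext[i], x$normalized$W_tot[i]))
  }
  invisible(x)
}

#' Flatten a work result to a one-row data frame
#'
#' One column per work component and exponent
#' (`W_int_b1`, `W_ext_b0.75`, ...), plus absolute works and metadata;
#' suitable for row-binding across subjects and writing to CSV.
#'
#' @param x A [compute_work()] result.
#' @param id Optional subject/trial identifier.
#' @return A one-row data frame.
#' @export
work_table <- function(x, id = NA_character_) {
  stopifnot(inherits(x, "work_result"))
  out <- data.frame(id = id, W_int_J = x$W_int_abs, W_ext_J = x$W_ext_abs,
                    W_tot_J = x$W_tot_abs, distance_m = x$distance,
                    mass_kg = x$M, n_strides = x$n_strides,
                    duration_s = x$duration, stringsAsFactors = FALSE)
  if (!is.null(x$normalized)) {
    for (i in seq_len(nrow(x$normalized))) {
      b <- x$normalized$b[i]
      out[[sprintf("W_int_b%g", b)]] <- x$normalized$W_int[i]
      out[[sprintf("W_ext_b%g", b)]] <- x$normalized$W_ext[i]
      out[[sprintf("W_tot_b%g", b)]] <- x$normalized$W_tot[i]
    }
  }
  out
}

#' Serialise a work result to JSON
#'
#' @param x A [compute_work()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_work_json <- function(x, path) {
  stopifnot(inherits(x, "work_result"))
  obj <- list(W_int_J = x$W_int_abs, W_ext_J = x$W_ext_abs,
              W_tot_J = x$W_tot_abs, per_limb_J = as.list(x$per_limb),
              distance_m = x$distance, mass_kg = x$M,
              n_strides = x$n_strides, duration_s = x$duration,
              normalized = x$normalized,
              cutoffs_hz = as.list(x$cutoffs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
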