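# Segment-wise pitch and roll kinetic energy from 3D marker tracks.
#
# Pitch kinetic energy of a rigid segment j is
#   KE_pitch,j = 1/2 I_yy,j w_y,j^2 + 1/2 m_j v_x,j^2
# and roll kinetic energy is
#   KE_roll,j  = 1/2 I_xx,j w_x,j^2 + 1/2 m_j v_y,j^2,
# with inertias and velocity components taken about/along the body fore-aft
# (x) and lateral (y) principal axes. Vertical translation and yaw do not
# contribute to pitching or rolling and are excluded by construction. Point
# masses (spheres added to the legs) contribute 1/2 m v_x^2 and 1/2 m v_y^2.
# Units: mm, g, s at the interface; energies in mJ (1 g mm^2 s^-2 = 1e-6 mJ).

KE_UNIT <- 1e-6  # g mm^2 s^-2 -> mJ

#' Construct a labelled 3D marker track
#'
#' @param data Data frame with columns `time_s`, `marker`, `x_mm`, `y_mm`,
#'   `z_mm`; every marker must be present at every time stamp (no gaps) and
#'   the frame rate must be constant.
#' @return A `marker_track` tibble with attribute `rate` (frames per second).
#' @export
marker_track <- function(data) {
  need <- c("time_s", "marker", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(data))) {
    rlang::abort(paste("marker track needs columns:", paste(need, collapse = ", ")),
                 class = "selfright_invalid_track")
  }
  times <- sort(unique(data$time_s))
  if (length(times) < 2L || any(diff(times) <= 0)) {
    rlang::abort("time stamps must be strictly increasing",
                 class = "selfright_invalid_track")
  }
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    rlang::abort("marker track must have a constant frame rate",
                 class = "selfright_invalid_track")
  }
  counts <- table(data$marker)
  if (length(unique(counts)) != 1L || counts[1] != length(times)) {
    rlang::abort("every marker must be labelled at every frame (gap-fill first)",
                 class = "selfright_gap_error")
  }
  out <- tibble::as_tibble(data[order(data$marker, data$time_s), need])
  structure(out, rate = 1 / stats::median(dt),
            class = c("marker_track", class(out)))
}

track_rate <- function(track) {
  attr(track, "rate") %||%
    (1 / stats::median(diff(sort(unique(track$time_s)))))
}

#' Zero-phase Butterworth low-pass filter of a marker track
#'
#' Each coordinate of each marker is filtered forward and backward
#' (zero phase) with a Butterworth low-pass design; defaults are a
#' sixth-order filter with a 25 Hz cut-off.
#'
#' @param track A [marker_track()].
#' @param cutoff Cut-off frequency (Hz); must be below the Nyquist rate.
#' @param order Filter order.
#' @export
filter_track <- function(track, cutoff = 25, order = 6) {
  rate <- track_rate(track)
  if (cutoff >= rate / 2) {
    rlang::abort("cutoff must be below the Nyquist frequency rate/2",
                 class = "selfright_parameter_error")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  smooth <- function(x) {
    # filtfilt is zero-phase; demean (exact DC passthrough, better numerical
    # conditioning at low relative cutoffs) and pad by reflection to tame
    # edge transients
    n <- length(x)
    mu <- mean(x)
    x <- x - mu
    np <- min(n - 1L, 3L * order * 10L)
    xp <- c(2 * x[1] - x[np:2], x, 2 * x[n] - x[(n - 1L):(n - np)])
    y <- signal::filtfilt(bf, xp)
    y[np:(np + n - 1L)] + mu
  }
  out <- track |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(x_mm = smooth(.data$x_mm), y_mm = smooth(.data$y_mm),
                  z_mm = smooth(.data$z_mm)) |>
    dplyr::ungroup()
  structure(out, rate = rate, class = c("marker_track", class(out)))
}

# central differences, one-sided at the ends; x may be a matrix (per column)
central_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) /
    (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Rigid-segment model of the animal for kinetic energy measurement
#'
#' The body is an ellipsoid cut into two parts at a fraction of total length
#' from the anterior end (default 38%), connected at the thorax-abdomen
#' joint on the midline, with uniform density; each hind leg is two rigid
#' rods (coxa-femur 0.07 g, tibia-tarsus 0.01 g) joined by spherical joints,
#' with an optional point sphere at the leg tip (0.14 g when the hind legs
#' are modified).
#'
#' @param spec Body [ellipsoid_spec()].
#' @param split_frac Cut position as a fraction of total length from the
#'   anterior end.
#' @param m_coxa_femur,m_tibia_tarsus Rod masses (g).
#' @param sphere_mass Added point mass at each leg tip (g); 0 for intact legs.
#' @param markers Named list mapping model landmarks to marker labels:
#'   `head`, `mid`, `abd`, `joint_left`, `joint_right`, `tip_left`,
#'   `tip_right`.
#' @export
animal_ke_model <- function(spec = animal_spec(), split_frac = 0.38,
                            m_coxa_femur = 0.07, m_tibia_tarsus = 0.01,
                            sphere_mass = 0,
                            markers = list(
                              head = "head", mid = "mid", abd = "abd",
                              joint_left = "joint_left",
                              joint_right = "joint_right",
                              tip_left = "tip_left", tip_right = "tip_right")) {
  parts <- split_ellipsoid_parts(spec, split_frac)
  structure(list(spec = spec, split_frac = split_frac,
                 m_coxa_femur = m_coxa_femur, m_tibia_tarsus = m_tibia_tarsus,
                 sphere_mass = sphere_mass, markers = markers, parts = parts),
            class = "animal_ke_model")
}

# uniform-density properties of the two ellipsoid parts cut at x = x_cut,
# from a deterministic quasi-random volume cloud: mass fraction, CoM x, and
# inertias about the part's own centroid (principal body axes)
split_ellipsoid_parts <- function(spec, split_frac, n = 40000L) {
  a <- spec$semi_a; b <- spec$semi_b; c_ <- spec$semi_c
  x_cut <- a - split_frac * 2 * a
  h <- halton_chunk(0L, 3L * n, 3) * 2 - 1
  h <- h[rowSums(h^2) <= 1, , drop = FALSE][seq_len(n), ]
  pts <- cbind(h[, 1] * a, h[, 2] * b, h[, 3] * c_)
  front <- pts[, 1] >= x_cut
  prop <- function(sel) {
    p <- pts[sel, , drop = FALSE]
    m <- spec$mass * nrow(p) / n
    com <- colMeans(p)
    pc <- sweep(p, 2, com)
    list(mass = m, com_x = com[1],
         Ixx = m * mean(pc[, 2]^2 + pc[, 3]^2),
         Iyy = m * mean(pc[, 1]^2 + pc[, 3]^2))
  }
  list(front = prop(front), rear = prop(!front), x_cut = x_cut)
}

marker_xyz <- function(track, label, times) {
  rows <- track[track$marker == label, ]
  if (nrow(rows) != length(times)) {
    rlang::abort(paste0("marker '", label, "' missing from track"),
                 class = "selfright_gap_error")
  }
  rows <- rows[order(rows$time_s), ]
  cbind(rows$x_mm, rows$y_mm, rows$z_mm)
}

#' Per-frame rigid-segment states from a marker track
#'
#' Estimates the body principal axes at each frame from the head-tip,
#' body-midpoint and abdomen-tip markers by Gram-Schmidt orthogonalisation,
#' reconstructs the two body ellipsoid parts and the four hind-leg rods (plus
#' optional tip spheres), and differentiates positions and axes by central
#' finite differences to obtain body-frame velocity components.
#'
#' @param track A (filtered) [marker_track()].
#' @param model An [animal_ke_model()].
#' @return A `segment_states` tibble: `time_s`, `object`, `type`, `m`,
#'   `Ixx`, `Iyy` (g mm^2), `wx`, `wy` (rad/s), `vx`, `vy` (mm/s).
#' @export
animal_segment_states <- function(track, model = animal_ke_model()) {
  mk <- model$markers
  times <- sort(unique(track$time_s))
  dt <- 1 / track_rate(track)
  head <- marker_xyz(track, mk$head, times)
  mid <- marker_xyz(track, mk$mid, times)
  abd <- marker_xyz(track, mk$abd, times)

  # body frame: x anterior along abdomen->head; z in the sagittal plane
  xb <- normalize_rows(head - abd)
  v2 <- mid - abd
  zb <- normalize_rows(v2 - rowSums(v2 * xb) * xb)
  yb <- cross_rows(zb, xb)

  a <- model$spec$semi_a
  center <- head - a * xb
  hip <- center + model$parts$x_cut * xb

  # body angular velocity from the rotating frame: w = sum over axes of
  # 1/2 e_i x de_i/dt for an orthonormal triad
  w_body <- 0.5 * (cross_rows(xb, central_diff(xb, dt)) +
                   cross_rows(yb, central_diff(yb, dt)) +
                   cross_rows(zb, central_diff(zb, dt)))

  seg_row <- function(object, m, Ixx, Iyy, w, v) {
    tibble::tibble(time_s = times, object = object, type = "segment",
                   m = m, Ixx = Ixx, Iyy = Iyy,
                   wx = rowSums(w * xb), wy = rowSums(w * yb),
                   vx = rowSums(v * xb), vy = rowSums(v * yb))
  }

  pr <- model$parts
  out <- list(
    seg_row("body_front", pr$front$mass, pr$front$Ixx, pr$front$Iyy, w_body,
            central_diff(center + pr$front$com_x * xb, dt)),
    seg_row("body_rear", pr$rear$mass, pr$rear$Ixx, pr$rear$Iyy, w_body,
            central_diff(center + pr$rear$com_x * xb, dt)))

  rod_states <- function(object, m, p0, p1) {
    d <- p1 - p0
    len2 <- rowSums(d^2)
    dhat <- d / sqrt(len2)
    # angular velocity of a rod (spin about its own axis is irrelevant:
    # the axial moment of inertia of a thin rod is zero)
    w <- cross_rows(dhat, central_diff(dhat, dt))
    L2 <- len2
    Ixx <- m * L2 / 12 * (1 - rowSums(dhat * xb)^2)
    Iyy <- m * L2 / 12 * (1 - rowSums(dhat * yb)^2)
    v <- central_diff((p0 + p1) / 2, dt)
    tibble::tibble(time_s = times, object = object, type = "segment",
                   m = m, Ixx = Ixx, Iyy = Iyy,
                   wx = rowSums(w * xb), wy = rowSums(w * yb),
                   vx = rowSums(v * xb), vy = rowSums(v * yb))
  }

  for (side in c("left", "right")) {
    joint <- marker_xyz(track, mk[[paste0("joint_", side)]], times)
    tip <- marker_xyz(track, mk[[paste0("tip_", side)]], times)
    out <- c(out, list(
      rod_states(paste0("coxa_femur_", side), model$m_coxa_femur, hip, joint),
      rod_states(paste0("tibia_tarsus_", side), model$m_tibia_tarsus, joint, tip)))
    if (model$sphere_mass > 0) {
      v <- central_diff(tip, dt)
      out <- c(out, list(tibble::tibble(
        time_s = times, object = paste0("sphere_", side), type = "sphere",
        m = model$sphere_mass, Ixx = 0, Iyy = 0, wx = 0, wy = 0,
        vx = rowSums(v * xb), vy = rowSums(v * yb))))
    }
  }
  st <- dplyr::bind_rows(out)
  structure(st, class = c("segment_states", class(st)))
}

#' Pitch and roll kinetic energy trace from segment states
#'
#' Sums the per-segment, per-sphere (and, for composite robots, per-cloud
#' point-mass) contributions at each frame.
#'
#' @param states A `segment_states` tibble (rows may mix types `"segment"`
#'   and `"sphere"`; point-cloud contributions enter as point-mass rows).
#' @return An `energy_trace` tibble: `time_s`, `ke_pitch_mJ`, `ke_roll_mJ`.
#' @export
ke_pitch_roll <- function(states) {
  out <- states |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      ke_pitch_mJ = KE_UNIT *
        sum(0.5 * .data$Iyy * .data$wy^2 + 0.5 * .data$m * .data$vx^2),
      ke_roll_mJ = KE_UNIT *
        sum(0.5 * .data$Ixx * .data$wx^2 + 0.5 * .data$m * .data$vy^2),
      .groups = "drop")
  structure(out, class = c("energy_trace", class(out)))
}

#' Time-averaged pitch and roll kinetic energy
#'
#' @param trace An `energy_trace`.
#' @param window Length-2 time window (s); defaults to the whole trace.
#' @return Named vector `c(pitch = , roll = )` in mJ.
#' @export
average_ke <- function(trace, window = range(trace$time_s)) {
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(sel)) {
    rlang::abort("averaging window contains no samples",
                 class = "selfright_domain_error")
  }
  c(pitch = mean(trace$ke_pitch_mJ[sel]), roll = mean(trace$ke_roll_mJ[sel]))
}

#' Kinetic energy minus potential energy barrier over time
#'
#' Subtracts, at each sample, the pitch and roll barriers evaluated at the
#' instantaneous wing-opening angle from the measured kinetic energies. The
#' attribute `max_surplus` reports the maximal surplus per direction over the
#' phase when the wings are held (nearly) fully open.
#'
#' @param trace An `energy_trace`.
#' @param curves A [barriers_vs_wing_opening()] result.
#' @param wing_profile Tibble `time_s`, `theta_wing_deg`, covering the trace.
#' @param open_frac Fraction of the peak wing angle defining the fully-open
#'   phase (default 0.99: wing angle within 1% of its plateau).
#' @return Tibble `time_s`, `theta_wing_deg`, `surplus_pitch_mJ`,
#'   `surplus_roll_mJ` with attribute `max_surplus`.
#' @export
ke_minus_barrier <- function(trace, curves, wing_profile, open_frac = 0.99) {
  rng <- range(wing_profile$time_s)
  if (min(trace$time_s) < rng[1] - 1e-9 || max(trace$time_s) > rng[2] + 1e-9) {
    rlang::abort("wing profile does not cover the energy trace",
                 class = "selfright_alignment_error")
  }
  th <- stats::approx(wing_profile$time_s, wing_profile$theta_wing_deg,
                      xout = trace$time_s)$y
  out <- tibble::tibble(
    time_s = trace$time_s,
    theta_wing_deg = th,
    surplus_pitch_mJ = trace$ke_pitch_mJ - barrier_at(curves, th, "pitch"),
    surplus_roll_mJ = trace$ke_roll_mJ - barrier_at(curves, th, "roll"))
  open <- th >= open_frac * max(th)
  attr(out, "max_surplus") <- c(
    pitch = if (any(open)) max(out$surplus_pitch_mJ[open]) else NA_real_,
    roll = if (any(open)) max(out$surplus_roll_mJ[open]) else NA_real_)
  out
}
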