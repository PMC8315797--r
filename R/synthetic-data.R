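# Synthetic inputs with the statistical structure the analysis assumes:
# marker tracks of a two-part ellipsoid body with rhythmically flailing
# hind-leg rods, noisy orientation/wing-angle traces of repeated righting
# attempts, and Monte-Carlo ensembles of barrier-crossing attempts. All
# generators are deterministic under a fixed seed.

#' Specification for the synthetic-data generators
#'
#' Defaults emulate the study conditions: 2000 frames/s marker tracks over
#' 2.5 s, leg flailing at 10 Hz (the ~100 ms flailing period), wing
#' opening-closing cycles at 2 Hz and leg oscillation at 2.5 Hz for
#' attempt traces, and 0.1 mm marker noise.
#'
#' @param body Body [ellipsoid_spec()].
#' @param rate Marker frame rate (frames/s).
#' @param duration Track duration (s).
#' @param leg_flail_frequency Hind-leg flailing frequency (Hz).
#' @param leg_amplitude Flailing amplitude (deg).
#' @param wing_cycle_frequency Wing opening-closing cycle rate (Hz).
#' @param leg_cycle_frequency Leg oscillation rate during attempts (Hz).
#' @param wing_amplitude Wing opening amplitude (deg).
#' @param noise_sd Additive Gaussian marker noise (mm).
#' @param orientation_noise_sd Orientation-trace noise (deg).
#' @param sphere_mass Added mass at each leg tip (g); 0 for intact legs.
#' @param n_attempts Wing cycles per orientation trace.
#' @param n_trials Trials for ensemble generators.
#' @param seed Integer seed fixing all randomness.
#' @param leg_geometry Named list: `L_coxa`, `L_tibia` (mm), `base_angle`,
#'   `knee_bend` (deg, coronal plane), `mid_offset` (mm, ventral offset of
#'   the body-midpoint marker that makes the body triad non-collinear).
#' @export
synth_spec <- function(body = animal_spec(), rate = 2000, duration = 2.5,
                       leg_flail_frequency = 10, leg_amplitude = 30,
                       wing_cycle_frequency = 2, leg_cycle_frequency = 2.5,
                       wing_amplitude = 72, noise_sd = 0.1,
                       orientation_noise_sd = 1, sphere_mass = 0,
                       n_attempts = 3, n_trials = 1, seed = 1,
                       leg_geometry = list(L_coxa = 12, L_tibia = 8,
                                           base_angle = 25, knee_bend = 30,
                                           mid_offset = 3)) {
  if (any(c(leg_flail_frequency, wing_cycle_frequency, leg_cycle_frequency,
            rate) <= 0)) {
    rlang::abort("frequencies and rate must be positive",
                 class = "selfright_domain_error")
  }
  if (noise_sd < 0 || orientation_noise_sd < 0) {
    rlang::abort("noise SDs must be non-negative",
                 class = "selfright_domain_error")
  }
  structure(
    list(body = body, rate = rate, duration = duration,
         leg_flail_frequency = leg_flail_frequency,
         leg_amplitude = leg_amplitude,
         wing_cycle_frequency = wing_cycle_frequency,
         leg_cycle_frequency = leg_cycle_frequency,
         wing_amplitude = wing_amplitude, noise_sd = noise_sd,
         orientation_noise_sd = orientation_noise_sd,
         sphere_mass = sphere_mass, n_attempts = n_attempts,
         n_trials = n_trials, seed = as.integer(seed),
         leg_geometry = leg_geometry),
    class = "synth_spec")
}

# coronal-plane leg direction and its derivative wrt the flail angle (rad)
leg_dir <- function(phi, side) cbind(0, side * sin(phi), cos(phi))
leg_dir_d <- function(phi, side) cbind(0, side * cos(phi), -sin(phi))

#' Generate a synthetic marker track with analytic ground-truth energetics
#'
#' The body (two-part ellipsoid, upside-down, stationary) carries two
#' hind legs, each two rigid rods in the coronal plane flailing sinusoidally
#' about the hip, with an optional point sphere at the tip. Markers are the
#' seven landmarks of [animal_ke_model()] plus additive Gaussian noise. The
#' ground-truth pitch/roll kinetic energy trace is evaluated analytically
#' from the generating motion (exact angles, rates and the same segment
#' energy decomposition), independent of the marker-based estimation path.
#'
#' @param spec A [synth_spec()].
#' @return List with `track` (a [marker_track()]), `truth` (an
#'   `energy_trace`), and `model` (the matching [animal_ke_model()]).
#' @export
gen_marker_tracks <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$leg_geometry
  b <- spec$body
  t <- seq(0, spec$duration, by = 1 / spec$rate)
  nt <- length(t)
  om <- 2 * pi * spec$leg_flail_frequency
  A <- spec$leg_amplitude * DEG
  phi0 <- g$base_angle * DEG
  bend <- g$knee_bend * DEG
  model <- animal_ke_model(spec = b, sphere_mass = spec$sphere_mass)
  x_cut <- model$parts$x_cut

  hip <- c(x_cut, 0, 0)
  landmarks <- list(
    head = matrix(rep(c(b$semi_a, 0, 0), each = nt), nt),
    mid = matrix(rep(c(x_cut, 0, g$mid_offset), each = nt), nt),
    abd = matrix(rep(c(-b$semi_a, 0, 0), each = nt), nt))

  truth_rows <- list()
  for (side_name in c("left", "right")) {
    side <- if (side_name == "left") +1 else -1
    phase <- if (side_name == "left") 0 else pi / 2
    phi <- phi0 + A * sin(om * t + phase)
    dphi <- A * om * cos(om * t + phase)
    d1 <- leg_dir(phi, side)
    d2 <- leg_dir(phi + bend, side)
    joint <- rep(hip, each = nt) + g$L_coxa * d1
    tip <- joint + g$L_tibia * d2
    landmarks[[paste0("joint_", side_name)]] <- joint
    landmarks[[paste0("tip_", side_name)]] <- tip

    # analytic ground truth: rods rotate in the coronal plane at rate dphi
    # about the body fore-aft axis; the body frame is the lab frame here
    vy1 <- dphi * (g$L_coxa / 2) * leg_dir_d(phi, side)[, 2]
    vy2 <- dphi * (g$L_coxa * leg_dir_d(phi, side)[, 2] +
                   (g$L_tibia / 2) * leg_dir_d(phi + bend, side)[, 2])
    vy_tip <- dphi * (g$L_coxa * leg_dir_d(phi, side)[, 2] +
                      g$L_tibia * leg_dir_d(phi + bend, side)[, 2])
    I1 <- model$m_coxa_femur * g$L_coxa^2 / 12
    I2 <- model$m_tibia_tarsus * g$L_tibia^2 / 12
    ke_roll <- 0.5 * I1 * dphi^2 + 0.5 * model$m_coxa_femur * vy1^2 +
      0.5 * I2 * dphi^2 + 0.5 * model$m_tibia_tarsus * vy2^2
    if (spec$sphere_mass > 0) {
      ke_roll <- ke_roll + 0.5 * spec$sphere_mass * vy_tip^2
    }
    truth_rows[[side_name]] <- ke_roll
  }
  truth <- tibble::tibble(
    time_s = t,
    ke_pitch_mJ = 0,
    ke_roll_mJ = KE_UNIT * (truth_rows$left + truth_rows$right))
  class(truth) <- c("energy_trace", class(truth))

  long <- purrr::imap_dfr(landmarks, function(m, name) {
    tibble::tibble(time_s = t, marker = name,
                   x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3])
  })
  if (spec$noise_sd > 0) {
    long <- withr::with_seed(spec$seed, {
      long$x_mm <- long$x_mm + stats::rnorm(nrow(long), 0, spec$noise_sd)
      long$y_mm <- long$y_mm + stats::rnorm(nrow(long), 0, spec$noise_sd)
      long$z_mm <- long$z_mm + stats::rnorm(nrow(long), 0, spec$noise_sd)
      long
    })
  }
  list(track = marker_track(long), truth = truth, model = model)
}

# smooth open-hold-close wing cycle, unit amplitude over one period
wing_cycle_shape <- function(u) {
  s <- numeric(length(u))
  ramp <- 0.3
  opening <- u < ramp
  hold <- u >= ramp & u < 1 - ramp
  closing <- u >= 1 - ramp
  s[opening] <- 0.5 * (1 - cos(pi * u[opening] / ramp))
  s[hold] <- 1
  s[closing] <- 0.5 * (1 - cos(pi * (1 - u[closing]) / ramp))
  s
}

#' Generate a synthetic orientation trace of repeated righting attempts
#'
#' Produces a yaw/pitch/roll time series at 0.01 s intervals together with
#' the matching wing-angle profile. Failed attempts pitch up toward the
#' metastable pitch as the wings open and fall back near (0, 0) as they
#' close; roll-success traces roll to +-180 deg during the final attempt;
#' pitch-success traces pitch through to 180 deg.
#'
#' @param spec A [synth_spec()].
#' @param outcome One of `"fail"`, `"roll-success"`, `"pitch-success"`.
#' @param metastable_gain Pitch of the metastable state as a fraction of the
#'   wing opening angle.
#' @return List with `trace` (`time_s`, `yaw_deg`, `pitch_deg`, `roll_deg`)
#'   and `wing` (`time_s`, `theta_wing_deg`).
#' @export
gen_orientation_trace <- function(spec,
                                  outcome = c("fail", "roll-success",
                                              "pitch-success"),
                                  metastable_gain = 0.55) {
  stopifnot(inherits(spec, "synth_spec"))
  outcome <- match.arg(outcome)
  period <- 1 / spec$wing_cycle_frequency
  t <- seq(0, spec$n_attempts * period - 0.01, by = 0.01)
  u <- (t / period) %% 1
  wing <- spec$wing_amplitude * wing_cycle_shape(u)
  pitch <- metastable_gain * wing
  roll <- numeric(length(t))

  if (outcome != "fail") {
    # escape during the hold phase of the final attempt and stay in the
    # upright basin afterwards
    t0 <- (spec$n_attempts - 1 + 0.35) * period
    esc <- t >= t0
    prog <- pmin((t[esc] - t0) / (0.5 * period), 1)
    step <- prog^2 * (3 - 2 * prog)
    if (outcome == "roll-success") {
      roll[esc] <- 180 * step
      pitch[esc] <- pitch[esc] * (1 - step)
    } else {
      pitch[esc] <- pitch[esc] + (180 - pitch[esc]) * step
    }
  }
  out <- withr::with_seed(spec$seed + 1L, {
    ns <- spec$orientation_noise_sd
    tibble::tibble(
      time_s = t,
      yaw_deg = stats::rnorm(length(t), 0, ns),
      pitch_deg = pitch + stats::rnorm(length(t), 0, ns),
      roll_deg = roll + stats::rnorm(length(t), 0, ns))
  })
  list(trace = out,
       wing = tibble::tibble(time_s = t, theta_wing_deg = wing))
}

#' Monte-Carlo simulation of barrier-crossing righting attempts
#'
#' Each attempt draws a roll kinetic energy from a zero-truncated Gaussian
#' whose mean grows with the square of the leg oscillation amplitude
#' (`mean = ke_coef * theta_leg^2`); the attempt succeeds if the draw reaches
#' the roll barrier at full wing opening. Trials repeat attempts up to
#' `max_attempts`; unsuccessful trials are censored at the cap.
#'
#' @param curves A [barriers_vs_wing_opening()] result for the body, or an
#'   [articulated_body()] (curves are then computed on a coarse grid).
#' @param theta_wing Wing opening amplitude (deg); must lie within the range
#'   of the barrier curves.
#' @param theta_leg Leg oscillation amplitude (deg).
#' @param ke_coef Mean roll kinetic energy per squared degree of leg
#'   amplitude (mJ/deg^2). The default gives 40 mJ at the maximal tested
#'   amplitude of 45 deg, the scale at which the robot always self-rights.
#' @param cv Coefficient of variation of the attempt-level energy draw.
#' @param n Number of trials.
#' @param seed Integer seed.
#' @param max_attempts Attempt cap per trial.
#' @return An `attempt_ensemble` object: per-attempt draws, per-trial
#'   attempts-to-success (censored at the cap), the success probability, and
#'   the parameters.
#' @export
simulate_attempts <- function(curves, theta_wing, theta_leg,
                              ke_coef = 40 / 45^2, cv = 0.3, n = 1000,
                              seed = 1, max_attempts = 50) {
  if (inherits(curves, "articulated_body")) {
    curves <- barriers_vs_wing_opening(curves, seq(0, 90, by = 10),
                                       pitch_step = 2, psi_step = 3)
  }
  if (theta_wing < min(curves$theta_wing_deg) - 1e-9 ||
      theta_wing > max(curves$theta_wing_deg) + 1e-9) {
    rlang::abort("roll barrier undefined at this wing opening angle",
                 class = "selfright_config_error")
  }
  barrier <- barrier_at(curves, theta_wing, "roll")
  mu <- ke_coef * theta_leg^2
  sd <- cv * mu
  draw_ke <- function(k) {
    if (sd == 0) return(rep(mu, k))
    p0 <- stats::pnorm(0, mu, sd)
    stats::qnorm(p0 + stats::runif(k) * (1 - p0), mu, sd)
  }
  res <- withr::with_seed(as.integer(seed), {
    rows <- vector("list", n)
    for (trial in seq_len(n)) {
      ke <- draw_ke(max_attempts)
      succ <- ke >= barrier
      k <- if (any(succ)) which(succ)[1] else max_attempts
      rows[[trial]] <- tibble::tibble(
        trial = trial, attempt = seq_len(k), ke_roll_mJ = ke[seq_len(k)],
        success = succ[seq_len(k)])
    }
    dplyr::bind_rows(rows)
  })
  attempts_to_success <- res |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(attempts = max(.data$attempt),
                     righted = any(.data$success), .groups = "drop")
  structure(
    list(attempts = res,
         attempts_to_success = attempts_to_success,
         probability = mean(res$success),
         roll_barrier_mJ = barrier,
         params = list(theta_wing = theta_wing, theta_leg = theta_leg,
                       ke_coef = ke_coef, cv = cv, n = n, seed = seed,
                       max_attempts = max_attempts)),
    class = "attempt_ensemble")
}

#' @export
print.attempt_ensemble <- function(x, ...) {
  cat("<attempt_ensemble> theta_wing =", x$params$theta_wing,
      "deg, theta_leg =", x$params$theta_leg, "deg\n")
  cat("  roll barrier:", format(x$roll_barrier_mJ, digits = 4), "mJ;",
      "attempts:", nrow(x$attempts), "\n")
  cat("  self-righting probability:", format(x$probability, digits = 3),
      "; mean attempts-to-success:",
      format(mean(x$attempts_to_success$attempts), digits = 3), "\n")
  invisible(x)
}
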