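# Directional escape barriers from the upside-down/metastable minimum.
#
# The escape direction in pitch-roll space is parameterised by the polar
# angle psi measured from the positive-pitch axis (psi = +-90 deg is pure
# roll). Along the straight ray from the metastable minimum, the barrier is
# the maximal increase of potential energy over the cross-section; rays run
# to the boundary of the [-180, 180]^2 chart.

#' Escape barrier along one direction in pitch-roll space
#'
#' @param grid A `landscape_grid`.
#' @param origin Length-2 vector `c(pitch, roll)` of the landscape minimum to
#'   escape from; defaults to the minimum nearest (0, 0).
#' @param psi Escape direction(s) in degrees from the positive-pitch axis.
#' @param ray_step Sampling step along the ray (deg); bilinear interpolation
#'   between grid nodes.
#' @return Barrier energy (mJ) per `psi`, clamped at zero.
#' @export
barrier_along_direction <- function(grid, origin = NULL, psi = 0,
                                    ray_step = 0.25) {
  origin <- origin %||% metastable_origin(grid)
  if (any(abs(origin) > 180)) {
    rlang::abort("origin outside the pitch-roll grid",
                 class = "selfright_domain_error")
  }
  e0 <- landscape_energy_at(grid, origin[1], origin[2], warn_wrap = FALSE)
  vapply(psi, function(p) {
    dp <- cos(p * DEG); dr <- sin(p * DEG)
    # ray length to the chart boundary
    tmax <- min(
      if (abs(dp) > 1e-12) max((c(-180, 180) - origin[1]) / dp) else Inf,
      if (abs(dr) > 1e-12) max((c(-180, 180) - origin[2]) / dr) else Inf)
    t <- seq(0, tmax, by = ray_step)
    e <- bilinear(grid$pitch, grid$roll, grid$energy,
                  origin[1] + t * dp, origin[2] + t * dr)
    max(0, max(e) - e0)
  }, 0)
}

# minimum nearest (0,0): the upside-down/metastable origin
metastable_origin <- function(grid) {
  mins <- find_minima(grid)
  d2 <- ang_diff(mins$pitch, 0)^2 + ang_diff(mins$roll, 0)^2
  c(mins$pitch[which.min(d2)], mins$roll[which.min(d2)])
}

#' Escape-barrier profile over all directions
#'
#' @inheritParams barrier_along_direction
#' @param psi_step Direction increment (deg); must divide 360.
#' @return A `barrier_profile` tibble with columns `psi_deg`, `barrier_mJ`
#'   and attributes `origin` and `theta_wing`.
#' @export
barrier_profile <- function(grid, origin = NULL, psi_step = 1,
                            ray_step = 0.25) {
  if (360 %% psi_step != 0) {
    rlang::abort("psi_step must divide 360 evenly",
                 class = "selfright_domain_error")
  }
  origin <- origin %||% metastable_origin(grid)
  psi <- seq(-180, 180 - psi_step, by = psi_step)
  out <- tibble::tibble(
    psi_deg = psi,
    barrier_mJ = barrier_along_direction(grid, origin, psi, ray_step))
  structure(out, origin = origin, theta_wing = grid$theta_wing,
            class = c("barrier_profile", class(out)))
}

#' Pitch and roll barriers from a directional profile
#'
#' The pitch barrier is the barrier at psi = 0 (toward the pitch-upright
#' minimum); the roll barrier is the lowest barrier within
#' psi in [45, 135] or [-135, -45] degrees (closed intervals), the angular
#' range containing the two roll-upright minima.
#'
#' @param profile A [barrier_profile()].
#' @return Named numeric vector `c(pitch = , roll = )` in mJ.
#' @export
pitch_roll_barriers <- function(profile) {
  psi <- profile$psi_deg
  if (!any(abs(psi) < 1e-9) || max(psi) < 135 || min(psi) > -135) {
    rlang::abort("profile must cover psi = 0 and psi = +-[45, 135]",
                 class = "selfright_domain_error")
  }
  in_roll <- (psi >= 45 & psi <= 135) | (psi >= -135 & psi <= -45)
  c(pitch = profile$barrier_mJ[which(abs(psi) < 1e-9)[1]],
    roll = min(profile$barrier_mJ[in_roll]))
}

#' Pitch and roll barriers versus wing-opening angle
#'
#' Sweeps the wing-opening angle, tracking the metastable minimum by
#' continuity from angle to angle, and measures the pitch and roll barriers
#' at each angle. For the default models both curves decrease monotonically
#' as the wings open, with the roll barrier below the pitch barrier.
#'
#' @param body An [articulated_body()].
#' @param theta_wing Ascending wing opening angles (deg) within [-10, 90].
#' @param pitch_step,roll_step Landscape grid increments (deg).
#' @param psi_step Barrier-profile direction increment (deg).
#' @param theta_leg Leg angle (deg) held during the sweep.
#' @return A `barrier_curves` tibble with `theta_wing_deg`,
#'   `pitch_barrier_mJ`, `roll_barrier_mJ`, `origin_pitch`, `origin_roll`.
#' @export
barriers_vs_wing_opening <- function(body, theta_wing = seq(0, 90, by = 5),
                                     pitch_step = 1, roll_step = pitch_step,
                                     psi_step = 1, theta_leg = 0) {
  if (is.unsorted(theta_wing) || min(theta_wing) < -10 || max(theta_wing) > 90) {
    rlang::abort("theta_wing must be ascending within [-10, 90]",
                 class = "selfright_domain_error")
  }
  prev <- c(0, 0)
  rows <- vector("list", length(theta_wing))
  for (i in seq_along(theta_wing)) {
    g <- compute_landscape(body, theta_wing[i], pitch_step, roll_step, theta_leg)
    mins <- find_minima(g)   # a plateau representative is a valid flat origin
    if (nrow(mins) == 0L) {
      rlang::warn("metastable basin lost; truncating barrier curves")
      rows <- rows[seq_len(i - 1L)]
      break
    }
    d2 <- ang_diff(mins$pitch, prev[1])^2 + ang_diff(mins$roll, prev[2])^2
    k <- which.min(d2)
    origin <- c(mins$pitch[k], mins$roll[k])
    pr <- pitch_roll_barriers(barrier_profile(g, origin, psi_step))
    rows[[i]] <- tibble::tibble(
      theta_wing_deg = theta_wing[i],
      pitch_barrier_mJ = pr[["pitch"]], roll_barrier_mJ = pr[["roll"]],
      origin_pitch = origin[1], origin_roll = origin[2])
    prev <- origin
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("barrier_curves", class(out)))
}

#' Interpolate a barrier curve at arbitrary wing angles
#'
#' @param curves A [barriers_vs_wing_opening()] result.
#' @param theta_wing Wing angles (deg) to evaluate at.
#' @param which One of `"roll"` or `"pitch"`.
#' @export
barrier_at <- function(curves, theta_wing, which = c("roll", "pitch")) {
  which <- match.arg(which)
  col <- paste0(which, "_barrier_mJ")
  stats::approx(curves$theta_wing_deg, curves[[col]], xout = theta_wing,
                rule = 2)$y
}
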