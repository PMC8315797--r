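# Gravitational potential energy landscapes over body pitch-roll space.
#
# The landscape is E = m g z_CoM with the body posed at (yaw = 0, pitch,
# roll), translated vertically so that its lowest surface point touches the
# ground (single-point support; the center of mass may translate only
# vertically). Yaw does not change the center-of-mass height, so the
# landscape is indexed by pitch and roll alone at each wing-opening angle.

# Support minimum (lowest world z over the body surface) and center-of-mass
# world z, evaluated for every row of the up-direction matrix W (n x 3).
# Returns list(min_z, com_z), each length n. Flat-ground fast path: only the
# third row of the body rotation is needed.
support_and_com <- function(body, config, W) {
  parts <- posed_parts(body, config)
  n <- nrow(W)
  min_z <- rep(Inf, n)
  com_z <- numeric(n)
  M <- body$total_mass
  for (p in parts) {
    zc <- drop(W %*% p$center)
    com_z <- com_z + p$mass *
      drop(W %*% (as.numeric(p$rotation %*% p$com_local) + p$center))
    part_min <- switch(p$kind,
      ellipsoid = , shell_slice = {
        E <- W %*% p$rotation
        E[, 1] <- E[, 1] * p$dims$a
        E[, 2] <- E[, 2] * p$dims$b
        E[, 3] <- E[, 3] * p$dims$c
        con <- if (p$kind == "shell_slice") p$constraints else NULL
        zc + sphere_linear_min(E, con)
      },
      cuboid = {
        d <- p$dims
        corners <- as.matrix(expand.grid(x = c(-1, 1) * d$lx / 2,
                                         y = c(-1, 1) * d$ly / 2,
                                         z = c(-1, 1) * d$lz / 2))
        P <- p$rotation %*% t(corners) + p$center
        z_all <- W %*% P
        do.call(pmin, as.data.frame(z_all))
      },
      rod = {
        ends <- rbind(c(-p$dims$length / 2, 0, 0), c(p$dims$length / 2, 0, 0))
        P <- p$rotation %*% t(ends) + p$center
        z_all <- W %*% P
        pmin(z_all[, 1], z_all[, 2])
      },
      point = zc)
    min_z <- pmin(min_z, part_min)
  }
  list(min_z = min_z, com_z = com_z / M)
}

# Surface/contact sample of a part in the body frame (for uneven ground).
contact_points_body <- function(p, n = 400L) {
  local_pts <- switch(p$kind,
    point = matrix(0, 1, 3),
    rod = {
      s <- seq(-0.5, 0.5, length.out = max(n, 2L)) * p$dims$length
      cbind(s, 0, 0)
    },
    cuboid = {
      d <- p$dims
      corners <- as.matrix(expand.grid(c(-1, 1) * d$lx / 2,
                                       c(-1, 1) * d$ly / 2,
                                       c(-1, 1) * d$lz / 2))
      h <- halton_seq(n, 3)
      faces <- cbind((h[, 1] - 0.5) * d$lx, (h[, 2] - 0.5) * d$ly,
                     sign(h[, 3] - 0.5) * d$lz / 2)
      rbind(corners, faces)
    },
    ellipsoid = , shell_slice = {
      m <- 0L; q <- matrix(numeric(0), 0, 3); offset <- 0L
      while (nrow(q) < n) {
        h <- halton_chunk(offset, 4L * n, 2)
        z0 <- 2 * h[, 1] - 1
        phi <- 2 * pi * h[, 2]
        r0 <- sqrt(pmax(1 - z0^2, 0))
        qq <- cbind(r0 * cos(phi), r0 * sin(phi), z0)
        if (p$kind == "shell_slice" && !is.null(p$constraints)) {
          keep <- rep(TRUE, nrow(qq))
          for (k in seq_len(nrow(p$constraints))) {
            cs <- p$constraints[k, ]
            keep <- keep & (cs$dir * qq[, cs$axis] >= cs$bound)
          }
          qq <- qq[keep, , drop = FALSE]
        }
        q <- rbind(q, qq)
        offset <- offset + 4L * n
      }
      q <- q[seq_len(n), , drop = FALSE]
      cbind(q[, 1] * p$dims$a, q[, 2] * p$dims$b, q[, 3] * p$dims$c)
    })
  t(p$rotation %*% t(local_pts) + p$center)
}

#' Sampled ground heightfield
#'
#' @param x,y Strictly increasing axis vectors (mm).
#' @param z Height matrix, `length(x)` by `length(y)` (mm); bilinear
#'   interpolation between samples, clamped at the edges.
#' @export
ground_heightfield <- function(x, y, z) {
  stopifnot(is.matrix(z), nrow(z) == length(x), ncol(z) == length(y))
  structure(list(x = x, y = y, z = z), class = "ground_heightfield")
}

#' Sinusoidal uneven-ground heightfield
#'
#' Convenience constructor for a doubly sinusoidal field of asperities,
#' `z = amplitude * sin(2 pi x / wavelength) * sin(2 pi y / wavelength)`.
#' @param amplitude Asperity amplitude (mm).
#' @param wavelength Asperity wavelength (mm).
#' @param extent Half-width of the sampled square (mm).
#' @param n Samples per axis.
#' @export
sinusoidal_ground <- function(amplitude, wavelength, extent = 4 * wavelength,
                              n = 121L) {
  ax <- seq(-extent, extent, length.out = n)
  z <- amplitude * outer(sin(2 * pi * ax / wavelength),
                         sin(2 * pi * ax / wavelength))
  ground_heightfield(ax, ax, z)
}

ground_height_at <- function(ground, x, y) {
  x <- pmin(pmax(x, ground$x[1]), ground$x[length(ground$x)])
  y <- pmin(pmax(y, ground$y[1]), ground$y[length(ground$y)])
  bilinear(ground$x, ground$y, ground$z, x, y)
}

# z_com over (pitch, roll) pairs on uneven ground: body centered over the
# heightfield origin, lifted by the minimal vertical translation achieving
# non-penetration at the sampled contact points.
zcom_on_ground <- function(body, config, pitch, roll, ground, contact_n = 400L) {
  parts <- posed_parts(body, config)
  clouds <- lapply(parts, contact_points_body, n = contact_n)
  com_b <- body_com(body, config)
  n <- length(pitch)
  out <- numeric(n)
  for (i in seq_len(n)) {
    R <- euler_rotation(0, pitch[i], roll[i])
    lift <- -Inf
    for (cl in clouds) {
      pw <- cl %*% t(R)
      g <- ground_height_at(ground, pw[, 1], pw[, 2])
      lift <- max(lift, max(g - pw[, 3]))
    }
    out[i] <- drop(R %*% com_b)[3] + lift
  }
  out
}

#' Center-of-mass height under ground contact
#'
#' Height (mm) of the center of mass when the body, posed at yaw = 0 and the
#' given pitch and roll, is translated vertically so its lowest surface point
#' touches the ground (or, with a heightfield, so that it just does not
#' penetrate the ground anywhere).
#'
#' @param body An [articulated_body()].
#' @param config A [configuration()].
#' @param pitch,roll Angles in degrees (vectorised, equal length).
#' @param ground Optional [ground_heightfield()].
#' @return Numeric vector of center-of-mass heights (mm).
#' @export
com_height <- function(body, config = configuration(), pitch = 0, roll = 0,
                       ground = NULL) {
  if (!inherits(body, "articulated_body") || length(body$parts) == 0L) {
    rlang::abort("body must be an articulated_body with at least one part",
                 class = "selfright_invalid_model")
  }
  stopifnot(length(pitch) == length(roll))
  if (!is.null(ground)) {
    return(zcom_on_ground(body, config, pitch, roll, ground))
  }
  sc <- support_and_com(body, config, up_rows(pitch, roll))
  sc$com_z - sc$min_z
}

#' Gravitational potential energy at a center-of-mass height
#'
#' `E = m g z_CoM`, reported in mJ for mass in g and height in mm.
#' @param body An [articulated_body()] (supplies mass and gravity).
#' @param z_com Center-of-mass height(s) in mm, >= 0.
#' @export
potential_energy <- function(body, z_com) {
  if (any(z_com < 0)) {
    rlang::abort("center-of-mass height must be non-negative",
                 class = "selfright_domain_error")
  }
  body$total_mass * body$gravity * z_com * 1e-3
}

#' Compute the potential energy landscape over pitch-roll space
#'
#' Energy at every node of a regular pitch-roll grid covering [-180, 180]^2
#' at the configured increments, at one wing-opening angle with the leg held
#' fixed (default: middle position).
#'
#' @param body An [articulated_body()].
#' @param theta_wing Wing opening angle (deg).
#' @param pitch_step,roll_step Grid increments (deg); must divide 360.
#' @param theta_leg Leg angle (deg) held during the sweep.
#' @param ground Optional [ground_heightfield()].
#' @return A `landscape_grid` object; see [tidy.landscape_grid()].
#' @export
compute_landscape <- function(body, theta_wing = 0, pitch_step = 1,
                              roll_step = pitch_step, theta_leg = 0,
                              ground = NULL) {
  if (360 %% pitch_step != 0 || 360 %% roll_step != 0) {
    rlang::abort("grid increments must divide 360 evenly",
                 class = "selfright_domain_error")
  }
  config <- configuration(theta_wing, theta_leg)
  pitch <- seq(-180, 180, by = pitch_step)
  roll <- seq(-180, 180, by = roll_step)
  nodes <- expand.grid(pitch = pitch, roll = roll)
  z <- com_height(body, config, nodes$pitch, nodes$roll, ground = ground)
  Z <- matrix(z, length(pitch), length(roll))
  datum <- if (is.null(ground)) 0 else min(ground$z)
  E <- potential_energy(body, pmax(Z - datum, 0))
  structure(
    list(pitch = pitch, roll = roll, z_com = Z, energy = E,
         theta_wing = theta_wing, theta_leg = theta_leg,
         mass = body$total_mass, gravity = body$gravity,
         ground = !is.null(ground), body_name = body$name),
    class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("<landscape_grid> ", x$body_name, " at theta_wing = ", x$theta_wing,
      " deg\n", sep = "")
  cat("  ", length(x$pitch), " x ", length(x$roll), " nodes, energy ",
      format(min(x$energy), digits = 4), " .. ",
      format(max(x$energy), digits = 4), " mJ\n", sep = "")
  invisible(x)
}

# interpolate energy at (pitch, roll), wrapping angles into [-180, 180]
landscape_energy_at <- function(grid, pitch, roll, warn_wrap = TRUE) {
  if (warn_wrap && any(abs(pitch) > 180 + 1e-9 | abs(roll) > 180 + 1e-9)) {
    rlang::warn("pitch/roll outside [-180, 180]; wrapping")
  }
  bilinear(grid$pitch, grid$roll, grid$energy, wrap180(pitch), wrap180(roll))
}

# toroidal neighbourhood minima on the (n-1)-periodic grid
#' Locate and classify local minima of a landscape
#'
#' Strict local minima under 8-neighbour comparison on the toroidally wrapped
#' grid (the duplicated -180/+180 rows and columns are one physical node).
#' Minima are classified by nearest canonical basin location; a minimum on the
#' roll = +-180 edge is reported at both signs (the two roll-upright basins).
#' On a degenerate constant (plateau) landscape no strict minimum exists and a
#' single plateau representative is returned with `plateau = TRUE`.
#'
#' @param grid A `landscape_grid`.
#' @return Tibble with `pitch`, `roll`, `energy`, `basin`, `plateau`.
#' @export
find_minima <- function(grid) {
  E <- grid$energy
  np <- length(grid$pitch); nr <- length(grid$roll)
  # reduced torus: drop the duplicated last row/column
  Et <- E[-np, -nr, drop = FALSE]
  n1 <- np - 1L; n2 <- nr - 1L
  is_min <- matrix(TRUE, n1, n2)
  ge_all <- matrix(TRUE, n1, n2)   # all neighbours >= (for plateau detection)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- Et[((seq_len(n1) - 1 + di) %% n1) + 1,
                  ((seq_len(n2) - 1 + dj) %% n2) + 1, drop = FALSE]
    is_min <- is_min & (Et < shifted - 1e-12)
    ge_all <- ge_all & (Et <= shifted + 1e-12)
  }
  idx <- which(is_min, arr.ind = TRUE)
  plateau <- FALSE
  if (nrow(idx) == 0L) {
    # plateau: represent the flat bottom by its centroid node
    plateau <- TRUE
    idx <- which(ge_all & Et <= min(Et) + 1e-12, arr.ind = TRUE)
    idx <- matrix(round(colMeans(idx)), 1, 2)
  }
  out <- tibble::tibble(
    pitch = grid$pitch[idx[, 1]],
    roll = grid$roll[idx[, 2]],
    energy = Et[idx],
    plateau = plateau)
  # canonical representation: the pitch edge is reported at +180
  out$pitch[abs(out$pitch + 180) < 1e-9] <- 180
  # The Z-Y'-X' Euler chart is redundant: (pitch, roll) and
  # (180 - pitch, roll + 180) describe the same orientation up to yaw, so the
  # upside-down/metastable minimum re-appears near the (+-180, +-180)
  # corners. Drop those duplicates.
  corner <- abs(out$pitch) > 135 & abs(out$roll) > 135
  if (any(corner) && !all(corner)) out <- out[!corner, ]
  # a minimum on the roll edge is reported at both -180 and +180
  edge <- abs(abs(out$roll) - 180) < 1e-9
  if (any(edge)) {
    dup <- out[edge, ]
    dup$roll <- -dup$roll
    out <- dplyr::bind_rows(out, dup)
    out <- dplyr::distinct(out, .data$pitch, .data$roll, .keep_all = TRUE)
  }
  out$basin <- classify_basin(out$pitch, out$roll)
  dplyr::arrange(out, .data$energy)[, c("pitch", "roll", "energy", "basin", "plateau")]
}

classify_basin <- function(pitch, roll) {
  dplyr::case_when(
    abs(roll) > 90 & roll > 0 ~ "roll-upright-right",
    abs(roll) > 90 ~ "roll-upright-left",
    pitch >= -180 & pitch < -162 ~ "backward",
    abs(pitch) > 90 ~ "pitch-upright",
    TRUE ~ "upside-down/metastable")
}

#' Track the metastable minimum across wing-opening angles
#'
#' Follows, by nearest-neighbour continuation in pitch-roll space, the local
#' minimum that is continuously connected to the upside-down minimum at
#' (0, 0) as the wings open. The sequence truncates with a warning if the
#' basin disappears.
#'
#' @param body An [articulated_body()].
#' @param theta_wing Ascending vector of wing opening angles (deg).
#' @param pitch_step,roll_step Landscape grid increments (deg).
#' @param theta_leg Leg angle (deg).
#' @param grids Optional pre-computed list of `landscape_grid`s matching
#'   `theta_wing` (computed when `NULL`).
#' @return Tibble with `theta_wing`, `pitch`, `roll`, `energy`.
#' @export
track_metastable <- function(body, theta_wing, pitch_step = 1,
                             roll_step = pitch_step, theta_leg = 0,
                             grids = NULL) {
  if (is.unsorted(theta_wing)) {
    rlang::abort("theta_wing sequence must be ascending",
                 class = "selfright_domain_error")
  }
  prev <- c(0, 0)
  rows <- vector("list", length(theta_wing))
  for (i in seq_along(theta_wing)) {
    g <- if (is.null(grids)) {
      compute_landscape(body, theta_wing[i], pitch_step, roll_step, theta_leg)
    } else grids[[i]]
    mins <- find_minima(g)   # a plateau representative still anchors tracking
    if (nrow(mins) == 0L) {
      rlang::warn("metastable basin lost; truncating sequence")
      rows <- rows[seq_len(i - 1L)]
      break
    }
    d2 <- ang_diff(mins$pitch, prev[1])^2 + ang_diff(mins$roll, prev[2])^2
    k <- which.min(d2)
    rows[[i]] <- tibble::tibble(theta_wing = theta_wing[i],
                                pitch = mins$pitch[k], roll = mins$roll[k],
                                energy = mins$energy[k])
    prev <- c(mins$pitch[k], mins$roll[k])
  }
  dplyr::bind_rows(rows)
}

# steepest-descent basin membership on the wrapped grid
#' Basin of attraction of a pitch-roll state
#'
#' Descends the wrapped landscape grid by repeatedly stepping to the lowest
#' 8-neighbour and returns the basin label of the minimum reached.
#' @param grid A `landscape_grid`.
#' @param pitch,roll State (deg); vectorised.
#' @export
basin_of <- function(grid, pitch, roll) {
  E <- grid$energy
  np <- length(grid$pitch); nr <- length(grid$roll)
  n1 <- np - 1L; n2 <- nr - 1L
  Et <- E[-np, -nr, drop = FALSE]
  step_p <- grid$pitch[2] - grid$pitch[1]
  step_r <- grid$roll[2] - grid$roll[1]
  vapply(seq_along(pitch), function(k) {
    i <- (round((wrap180(pitch[k]) + 180) / step_p) %% n1) + 1L
    j <- (round((wrap180(roll[k]) + 180) / step_r) %% n2) + 1L
    repeat {
      best <- c(i, j); bv <- Et[i, j]
      for (di in -1:1) for (dj in -1:1) {
        ii <- ((i - 1L + di) %% n1) + 1L
        jj <- ((j - 1L + dj) %% n2) + 1L
        if (Et[ii, jj] < bv - 1e-12) { bv <- Et[ii, jj]; best <- c(ii, jj) }
      }
      if (best[1] == i && best[2] == j) break
      i <- best[1]; j <- best[2]
    }
    classify_basin(grid$pitch[i], grid$roll[j])
  }, character(1))
}

#' Project a measured orientation trace onto evolving landscapes
#'
#' For each sample the landscape at the nearest available wing-opening angle
#' supplies the potential energy at the instantaneous body pitch and roll.
#' Only the trajectory end point carries the instantaneous-energy
#' interpretation; earlier samples show how pitch and roll evolved.
#'
#' @param grids List of `landscape_grid`s (one per wing angle).
#' @param trace Data frame with columns `time_s`, `pitch_deg`, `roll_deg` and
#'   `theta_wing_deg` (see [align_wing_profile()]).
#' @return Tibble `time_s`, `pitch_deg`, `roll_deg`, `theta_wing_deg`,
#'   `energy_mJ`, plus attribute `final_basin`.
#' @export
project_trajectory <- function(grids, trace) {
  need <- c("time_s", "pitch_deg", "roll_deg", "theta_wing_deg")
  if (!all(need %in% names(trace))) {
    rlang::abort(paste("trace must have columns:", paste(need, collapse = ", ")),
                 class = "selfright_alignment_error")
  }
  thetas <- vapply(grids, `[[`, 0, "theta_wing")
  gi <- vapply(trace$theta_wing_deg,
               function(th) which.min(abs(thetas - th)), 1L)
  if (any(abs(trace$pitch_deg) > 180 | abs(trace$roll_deg) > 180)) {
    rlang::warn("pitch/roll outside [-180, 180]; wrapping onto the landscape")
  }
  e <- vapply(seq_len(nrow(trace)), function(k) {
    landscape_energy_at(grids[[gi[k]]], trace$pitch_deg[k], trace$roll_deg[k],
                        warn_wrap = FALSE)
  }, 0)
  out <- tibble::tibble(
    time_s = trace$time_s,
    pitch_deg = wrap180(trace$pitch_deg),
    roll_deg = wrap180(trace$roll_deg),
    theta_wing_deg = trace$theta_wing_deg,
    energy_mJ = e)
  last <- nrow(out)
  attr(out, "final_basin") <- basin_of(grids[[gi[last]]],
                                       out$pitch_deg[last], out$roll_deg[last])
  out
}

#' Time-align a wing-angle profile with an orientation trace
#'
#' Linearly interpolates the wing profile at the trace timestamps and appends
#' a `theta_wing_deg` column.
#' @param trace Tibble with `time_s`, `pitch_deg`, `roll_deg`.
#' @param wing Tibble with `time_s`, `theta_wing_deg`.
#' @export
align_wing_profile <- function(trace, wing) {
  trace$theta_wing_deg <- stats::approx(wing$time_s, wing$theta_wing_deg,
                                        xout = trace$time_s, rule = 2)$y
  trace
}
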