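# Parametric self-deforming body models.
#
# A body is a collection of rigid parts (solid ellipsoids, slices of a
# zero-thickness ellipsoidal shell, cuboids, rods, point masses), each with a
# mass and a rigid transform into the body frame, plus joint rules that map a
# wing-opening angle and a leg angle to extra rigid transforms of the wing and
# leg parts. Units at the interface are mm, g and degrees; energies are mJ.
#
# Body-frame convention: +x anterior (toward the head), +z ventral, so a body
# at pose (yaw, pitch, roll) = (0, 0, 0) is resting upside-down with its
# dorsal shell on the ground, matching how overturned orientations are indexed
# in the pitch-roll landscape. Positive pitch lowers the head.

#' Ellipsoid body specification
#'
#' @param semi_a,semi_b,semi_c Semi-axes in mm (fore-aft, lateral,
#'   dorsoventral). For the default animal these are 26.5, 11.5 and 4 mm
#'   (body length 53, width 23, thickness 8 mm).
#' @param mass Body mass in g.
#' @return A list of class `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(semi_a, semi_b, semi_c, mass) {
  if (!all(is.finite(c(semi_a, semi_b, semi_c, mass))) ||
      any(c(semi_a, semi_b, semi_c) <= 0)) {
    rlang::abort("ellipsoid semi-axes must be positive and finite",
                 class = "selfright_invalid_shape")
  }
  if (mass <= 0) {
    rlang::abort("ellipsoid mass must be positive", class = "selfright_invalid_shape")
  }
  structure(list(semi_a = semi_a, semi_b = semi_b, semi_c = semi_c, mass = mass),
            class = "ellipsoid_spec")
}

#' Default discoid-cockroach body spec (53 x 23 x 8 mm, 2.6 g)
#'
#' Mass defaults to the mean intact body mass (2.6 g); pass `mass = 2.84` to
#' include the mass added to the hind legs.
#' @param mass Body mass in g.
#' @export
animal_spec <- function(mass = 2.6) ellipsoid_spec(26.5, 11.5, 4, mass)

part_kinds <- c("ellipsoid", "shell_slice", "cuboid", "rod", "point")

#' Construct a rigid body part
#'
#' @param kind One of `"ellipsoid"` (solid), `"shell_slice"` (zero-thickness
#'   region of an ellipsoid surface), `"cuboid"`, `"rod"` (along local x) or
#'   `"point"`.
#' @param dims Named list of dimensions in mm: ellipsoid/shell_slice need
#'   `a`, `b`, `c`; cuboid needs `lx`, `ly`, `lz`; rod needs `length`; point
#'   needs none.
#' @param mass Part mass in g (>= 0).
#' @param center Part-frame origin expressed in the body frame (mm).
#' @param rotation 3x3 rotation of the part frame into the body frame.
#' @param constraints For shell slices, a data frame with columns `axis`
#'   (1-3), `dir` (+1/-1) and `bound`, restricting the unit-sphere preimage q
#'   of the surface to `dir * q[axis] >= bound`.
#' @param role Joint-rule key: parts with role `"wing_left"`, `"wing_right"`
#'   or `"leg"` move with the wing/leg joint rules.
#' @param label Free-text part name.
#' @export
part_shape <- function(kind, dims = list(), mass, center = c(0, 0, 0),
                       rotation = diag(3), constraints = NULL,
                       role = "body", label = kind) {
  kind <- match.arg(kind, part_kinds)
  if (!is.finite(mass) || mass < 0) {
    rlang::abort("part mass must be non-negative", class = "selfright_invalid_shape")
  }
  need <- switch(kind,
    ellipsoid = , shell_slice = c("a", "b", "c"),
    cuboid = c("lx", "ly", "lz"),
    rod = "length",
    point = character(0))
  if (!all(need %in% names(dims))) {
    rlang::abort(paste0("part kind '", kind, "' needs dimensions: ",
                        paste(need, collapse = ", ")),
                 class = "selfright_invalid_shape")
  }
  dv <- unlist(dims[need])
  if (length(dv) && (!all(is.finite(dv)) || any(dv <= 0))) {
    rlang::abort("part dimensions must be positive", class = "selfright_invalid_shape")
  }
  if (kind == "shell_slice" && !is.null(constraints)) {
    bad <- abs(constraints$bound) >= 1 | !constraints$axis %in% 1:3 |
      !constraints$dir %in% c(-1, 1)
    if (any(bad)) {
      rlang::abort("shell-slice constraints must have |bound| < 1, axis in 1:3",
                   class = "selfright_invalid_geometry")
    }
  }
  p <- structure(
    list(label = label, role = role, kind = kind, dims = dims, mass = mass,
         center = as.numeric(center), rotation = rotation,
         constraints = constraints, com_local = c(0, 0, 0)),
    class = "righting_part")
  if (kind == "shell_slice") {
    cl <- discretize_part(p, 4000L)
    w <- if (sum(cl$mass) > 0) cl$mass else rep(1, nrow(cl))
    p$com_local <- c(sum(cl$x * w), sum(cl$y * w), sum(cl$z * w)) / sum(w)
  }
  p
}

#' Articulated self-deforming body
#'
#' @param parts List of [part_shape()] objects.
#' @param wing_rule,leg_rule Functions mapping an opening angle (deg) to a
#'   named list of joint transforms `list(<role> = list(R = <3x3>,
#'   origin = <hinge point>))`; [identity_rule()] freezes a joint.
#' @param gravity Gravitational acceleration in m s^-2.
#' @param name Model name used in printouts and run manifests.
#' @return A list of class `articulated_body` with `total_mass` equal to the
#'   sum of part masses.
#' @export
articulated_body <- function(parts, wing_rule = identity_rule(),
                             leg_rule = identity_rule(), gravity = 9.81,
                             name = "body") {
  stopifnot(length(parts) > 0)
  if (!all(vapply(parts, inherits, TRUE, "righting_part"))) {
    rlang::abort("all parts must be created with part_shape()",
                 class = "selfright_invalid_shape")
  }
  structure(
    list(parts = parts, wing_rule = wing_rule, leg_rule = leg_rule,
         total_mass = sum(vapply(parts, `[[`, 0, "mass")),
         gravity = gravity, name = name),
    class = "articulated_body")
}

#' @export
print.articulated_body <- function(x, ...) {
  cat("<articulated_body> ", x$name, "\n", sep = "")
  cat("  parts: ", length(x$parts), "  total mass: ",
      format(x$total_mass), " g\n", sep = "")
  for (p in x$parts) {
    cat("  - ", p$label, " (", p$kind, ", ", format(p$mass), " g, role ",
        p$role, ")\n", sep = "")
  }
  invisible(x)
}

#' Joint rule that leaves all parts fixed
#' @export
identity_rule <- function() function(theta) list()

#' Symmetric wing-opening joint rule
#'
#' Both wings open by rolling and pitching about the body by the same angle:
#' the left wing rotates by `Ry(-theta) Rx(+theta)` about the hinge point and
#' the right wing by its sagittal mirror image. The pitch component swings
#' the posterior wing tips dorsally (into the ground when the body is
#' upside-down, pitching the body up), while the roll component lifts the
#' lateral wing edges ventrally, away from the ground, which lowers the roll
#' barrier as the wings open.
#'
#' @param hinge Hinge point in the body frame (mm).
#' @export
make_wing_rule <- function(hinge = c(0, 0, 0)) {
  force(hinge)
  function(theta) {
    list(
      wing_left = list(R = rot_y(-theta) %*% rot_x(theta), origin = hinge),
      wing_right = list(R = rot_y(-theta) %*% rot_x(-theta), origin = hinge))
  }
}

#' Coronal-plane leg oscillation rule
#'
#' Rotates parts with role `"leg"` about the body fore-aft axis through the
#' hinge point, i.e. a pendulum swing in the coronal plane.
#' @param hinge Hinge point in the body frame (mm).
#' @export
make_leg_rule <- function(hinge = c(0, 0, 0)) {
  force(hinge)
  function(theta) list(leg = list(R = rot_x(theta), origin = hinge))
}

#' Wing/leg configuration of a self-deforming body
#'
#' @param theta_wing Wing opening amplitude in degrees, within [-10, 90].
#' @param theta_leg Leg angle in degrees, within [-45, 45].
#' @export
configuration <- function(theta_wing = 0, theta_leg = 0) {
  if (!is.finite(theta_wing) || theta_wing < -10 || theta_wing > 90) {
    rlang::abort("theta_wing must lie in [-10, 90] degrees",
                 class = "selfright_domain_error")
  }
  if (!is.finite(theta_leg) || abs(theta_leg) > 45) {
    rlang::abort("theta_leg must lie in [-45, 45] degrees",
                 class = "selfright_domain_error")
  }
  structure(list(theta_wing = theta_wing, theta_leg = theta_leg),
            class = "righting_configuration")
}

# Apply joint rules at a configuration: returns parts with body-frame
# rotation/center updated. Joint transform about hinge h: R' = Rj R,
# c' = Rj (c - h) + h.
posed_parts <- function(body, config) {
  joints <- c(body$wing_rule(config$theta_wing), body$leg_rule(config$theta_leg))
  lapply(body$parts, function(p) {
    j <- joints[[p$role]]
    if (!is.null(j)) {
      p$rotation <- j$R %*% p$rotation
      p$center <- as.numeric(j$R %*% (p$center - j$origin) + j$origin)
    }
    p
  })
}

# ---------------------------------------------------------------------------
# discretization into point-mass clouds

#' Discretize a part into a point-mass cloud
#'
#' Points are drawn from a deterministic Halton sequence (surface points for
#' shell slices, volume points for solids) in the part's local frame; point
#' masses sum exactly to the part mass. Shell-slice point masses are weighted
#' by the ellipsoid surface area element so the cloud represents a uniform
#' surface density.
#'
#' @param part A [part_shape()].
#' @param resolution Requested number of points (>= 10; degenerate kinds such
#'   as `"point"` return fewer).
#' @return A tibble with columns `x`, `y`, `z` (mm, part frame) and `mass` (g).
#' @export
discretize_part <- function(part, resolution = 400L) {
  if (!inherits(part, "righting_part")) {
    rlang::abort("part must be a righting_part", class = "selfright_invalid_shape")
  }
  n <- as.integer(resolution)
  if (part$kind != "point" && n < 10L) {
    rlang::abort("resolution must be at least 10 points",
                 class = "selfright_domain_error")
  }
  d <- part$dims
  cloud <- switch(part$kind,
    point = tibble::tibble(x = 0, y = 0, z = 0, mass = part$mass),
    rod = {
      s <- (seq_len(n) - 0.5) / n - 0.5
      tibble::tibble(x = s * d$length, y = 0, z = 0, mass = part$mass / n)
    },
    cuboid = {
      # antithetic pairs: the centrally mirrored twin of every point keeps
      # the cloud centroid exactly at the centroid of the shape
      m <- ceiling(n / 2)
      h <- halton_seq(m, 3) - 0.5
      h <- rbind(h, -h)
      tibble::tibble(x = h[, 1] * d$lx, y = h[, 2] * d$ly, z = h[, 3] * d$lz,
                     mass = part$mass / nrow(h))
    },
    ellipsoid = {
      m <- ceiling(n / 2)
      pts <- matrix(numeric(0), 0, 3)
      offset <- 0L
      while (nrow(pts) < m) {
        chunk <- 4L * n
        h <- halton_chunk(offset, chunk, 3) * 2 - 1
        keep <- rowSums(h^2) <= 1
        pts <- rbind(pts, h[keep, , drop = FALSE])
        offset <- offset + chunk
      }
      pts <- pts[seq_len(m), , drop = FALSE]
      pts <- rbind(pts, -pts)
      tibble::tibble(x = pts[, 1] * d$a, y = pts[, 2] * d$b, z = pts[, 3] * d$c,
                     mass = part$mass / nrow(pts))
    },
    shell_slice = {
      q <- matrix(numeric(0), 0, 3)
      offset <- 0L
      while (nrow(q) < n) {
        chunk <- 8L * n
        h <- halton_chunk(offset, chunk, 2)
        z0 <- 2 * h[, 1] - 1
        phi <- 2 * pi * h[, 2]
        r0 <- sqrt(pmax(1 - z0^2, 0))
        qq <- cbind(r0 * cos(phi), r0 * sin(phi), z0)
        keep <- rep(TRUE, nrow(qq))
        if (!is.null(part$constraints)) {
          for (k in seq_len(nrow(part$constraints))) {
            cs <- part$constraints[k, ]
            keep <- keep & (cs$dir * qq[, cs$axis] >= cs$bound)
          }
        }
        q <- rbind(q, qq[keep, , drop = FALSE])
        offset <- offset + chunk
      }
      q <- q[seq_len(n), , drop = FALSE]
      w <- sqrt((q[, 1] / d$a)^2 + (q[, 2] / d$b)^2 + (q[, 3] / d$c)^2)
      tibble::tibble(x = q[, 1] * d$a, y = q[, 2] * d$b, z = q[, 3] * d$c,
                     mass = part$mass * w / sum(w))
    })
  cloud
}

# Halton points with an index offset (deterministic continuation).
halton_chunk <- function(offset, n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13)
  out <- matrix(0, n, dim)
  for (dd in seq_len(dim)) {
    b <- primes[dd]
    i <- offset + seq_len(n)
    h <- numeric(n)
    f <- 1 / b
    while (any(i > 0)) {
      h <- h + f * (i %% b)
      i <- i %/% b
      f <- f / b
    }
    out[, dd] <- h
  }
  out
}

#' Pose the full body point cloud in the world frame
#'
#' Applies the wing/leg joint rules, then the intrinsic Z-Y'-X' body rotation.
#' The cloud is returned before ground contact, i.e. with the body-frame
#' origin at the world origin.
#'
#' @param body An [articulated_body()].
#' @param config A [configuration()].
#' @param pose Named list or vector with `yaw`, `pitch`, `roll` in degrees.
#' @param resolution Points per part.
#' @return Tibble with `part`, `role`, `x`, `y`, `z` (mm) and `mass` (g).
#' @export
pose_points <- function(body, config = configuration(),
                        pose = c(yaw = 0, pitch = 0, roll = 0),
                        resolution = 400L) {
  pose <- as.list(pose)
  R <- euler_rotation(pose$yaw %||% 0, pose$pitch %||% 0, pose$roll %||% 0)
  parts <- posed_parts(body, config)
  purrr::map_dfr(parts, function(p) {
    cl <- discretize_part(p, resolution)
    m <- R %*% (p$rotation %*% t(cbind(cl$x, cl$y, cl$z)) + p$center)
    tibble::tibble(part = p$label, role = p$role,
                   x = m[1, ], y = m[2, ], z = m[3, ], mass = cl$mass)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# model builders

#' Build the rigid-ellipsoid animal model
#'
#' The body is a solid ellipsoid carrying (by default) the whole mass, so the
#' center of mass sits at the geometric center; the wings are zero-thickness
#' slices of the same ellipsoidal shell - the dorsal shell above a horizontal
#' cut, split sagittally - so that with wings closed the outer surface is
#' exactly the full ellipsoid.
#'
#' @param spec An [ellipsoid_spec()]; defaults to [animal_spec()].
#' @param wing_mass Mass in g of each wing slice (default 0: the wings shape
#'   the contact surface without moving the center of mass).
#' @param wing_cut_height Dorsoventral height fraction of the horizontal cut
#'   delimiting the wing slices, in [0, 1).
#' @param hinge_frac Fore-aft hinge position as a fraction of `semi_a`.
#' @export
build_animal_model <- function(spec = animal_spec(), wing_mass = 0,
                               wing_cut_height = 0.5, hinge_frac = 0.5) {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  if (wing_cut_height < 0 || wing_cut_height >= 1) {
    rlang::abort("wing slices may not exceed half the shell: wing_cut_height must be in [0, 1)",
                 class = "selfright_invalid_geometry")
  }
  dims <- list(a = spec$semi_a, b = spec$semi_b, c = spec$semi_c)
  body_mass <- spec$mass - 2 * wing_mass
  if (body_mass <= 0) {
    rlang::abort("wing masses exceed total mass", class = "selfright_invalid_shape")
  }
  # dorsal (= local -z) shell above the horizontal cut, split at the sagittal plane
  wing_con <- function(side) data.frame(
    axis = c(3L, 2L), dir = c(-1, side), bound = c(wing_cut_height, 0))
  parts <- list(
    part_shape("ellipsoid", dims, body_mass, label = "body"),
    part_shape("shell_slice", dims, wing_mass, constraints = wing_con(+1),
               role = "wing_left", label = "wing_left"),
    part_shape("shell_slice", dims, wing_mass, constraints = wing_con(-1),
               role = "wing_right", label = "wing_right"))
  articulated_body(parts,
                   wing_rule = make_wing_rule(c(hinge_frac * spec$semi_a, 0, 0)),
                   name = "animal")
}

#' Default robot part masses (g)
#'
#' Head 13.4, leg rod 4.3, leg added mass 51.5, leg motor 28.6, two wings
#' 57.4, two wing pitch motors 56.0, two wing roll motors 48.8; total 260 g.
#' @export
robot_part_masses <- function() {
  c(head = 13.4, leg_rod = 4.3, leg_added_mass = 51.5, leg_motor = 28.6,
    wings = 57.4, wing_pitch_motors = 56.0, wing_roll_motors = 48.8)
}

#' Build the robot-like composite model
#'
#' A thin ellipsoidal dorsal half-shell cut into a head (anterior of a
#' transverse cut) and two wings (posterior, split sagittally), plus a ventral
#' pendulum leg rod with an added point mass, and five motors modelled as
#' solid cuboids. Internal part placement is not published for the original
#' robot; the defaults put the wing pitch motors on the transverse hinge line,
#' the wing roll motors along the sagittal hinge line, all motors against the
#' dorsal shell interior, and the leg added-mass carriage at mid-rod.
#'
#' @param semi_axes Shell semi-axes `c(a, b, c)` in mm (default 130, 110,
#'   21.5: a 260 x 220 x 43 mm shell).
#' @param part_masses Named masses in g; see [robot_part_masses()].
#' @param placement Optional named list overriding geometry defaults:
#'   `head_cut` (sphere-space transverse cut, default 0.35), `leg_length`
#'   (mm), `mass_position` (added-mass distance along the leg, mm),
#'   `motor_dims` (cuboid mm), `motor_depth` (dorsoventral motor center, mm).
#' @export
build_robot_model <- function(semi_axes = c(130, 110, 21.5),
                              part_masses = robot_part_masses(),
                              placement = list()) {
  need <- names(robot_part_masses())
  if (!all(need %in% names(part_masses))) {
    rlang::abort(paste("missing robot part masses:",
                       paste(setdiff(need, names(part_masses)), collapse = ", ")),
                 class = "selfright_config_error")
  }
  pm <- part_masses[need]
  a <- semi_axes[1]; b <- semi_axes[2]; c_ <- semi_axes[3]
  dims <- list(a = a, b = b, c = c_)
  pl <- utils::modifyList(list(
    head_cut = 0.35, leg_length = 100, mass_position = 45,
    motor_dims = list(lx = 36, ly = 27, lz = 24), motor_depth = -6), placement)
  s0 <- pl$head_cut
  hinge_x <- s0 * a
  zm <- pl$motor_depth
  md <- pl$motor_dims

  dorsal <- data.frame(axis = 3L, dir = -1, bound = 0)
  head_con <- rbind(dorsal, data.frame(axis = 1L, dir = +1, bound = s0))
  wing_con <- function(side) rbind(
    dorsal,
    data.frame(axis = c(1L, 2L), dir = c(-1, side), bound = c(-s0, 0)))

  rodL <- pl$leg_length
  parts <- list(
    part_shape("shell_slice", dims, pm[["head"]], constraints = head_con,
               label = "head"),
    part_shape("shell_slice", dims, pm[["wings"]] / 2, constraints = wing_con(+1),
               role = "wing_left", label = "wing_left"),
    part_shape("shell_slice", dims, pm[["wings"]] / 2, constraints = wing_con(-1),
               role = "wing_right", label = "wing_right"),
    # ventral pendulum leg: rod along +z from the hinge at the body origin
    part_shape("rod", list(length = rodL), pm[["leg_rod"]],
               center = c(0, 0, rodL / 2), rotation = rot_y(-90),
               role = "leg", label = "leg_rod"),
    part_shape("point", mass = pm[["leg_added_mass"]],
               center = c(0, 0, pl$mass_position), role = "leg",
               label = "leg_added_mass"),
    part_shape("cuboid", md, pm[["leg_motor"]], center = c(-40, 0, zm),
               label = "leg_motor"),
    part_shape("cuboid", md, pm[["wing_pitch_motors"]] / 2,
               center = c(hinge_x, 35, zm), label = "wing_pitch_motor_L"),
    part_shape("cuboid", md, pm[["wing_pitch_motors"]] / 2,
               center = c(hinge_x, -35, zm), label = "wing_pitch_motor_R"),
    part_shape("cuboid", md, pm[["wing_roll_motors"]] / 2,
               center = c(-30, 20, zm), label = "wing_roll_motor_L"),
    part_shape("cuboid", md, pm[["wing_roll_motors"]] / 2,
               center = c(-30, -20, zm), label = "wing_roll_motor_R"))
  articulated_body(parts,
                   wing_rule = make_wing_rule(c(hinge_x, 0, 0)),
                   leg_rule = make_leg_rule(c(0, 0, 0)),
                   name = "robot")
}

#' Uniform solid-ellipsoid body (no articulated appendages)
#'
#' Convenience builder used for closed-form oracles and degenerate cases such
#' as a sphere, whose pitch and roll barriers are both zero.
#' @param spec An [ellipsoid_spec()].
#' @export
build_ellipsoid_body <- function(spec) {
  stopifnot(inherits(spec, "ellipsoid_spec"))
  dims <- list(a = spec$semi_a, b = spec$semi_b, c = spec$semi_c)
  articulated_body(list(part_shape("ellipsoid", dims, spec$mass, label = "body")),
                   name = "ellipsoid")
}

# body center of mass in the body frame at a configuration
body_com <- function(body, config = configuration()) {
  parts <- posed_parts(body, config)
  M <- body$total_mass
  com <- c(0, 0, 0)
  for (p in parts) {
    com <- com + p$mass * (as.numeric(p$rotation %*% p$com_local) + p$center)
  }
  com / M
}
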