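# Shared fixtures, built in code: default models, coarse grids for speed,
# and closed-form oracles.

G <- 9.81
MJ <- 1e-3  # g * (m/s^2) * mm -> mJ

# closed-form support height of a solid ellipsoid resting on a plane:
# h(pitch, roll) = sqrt(a^2 w1^2 + b^2 w2^2 + c^2 w3^2) with w the world-up
# direction expressed in the body frame (third row of the Euler rotation)
ellipsoid_support <- function(a, b, c_, pitch, roll) {
  bR <- pitch * pi / 180
  gR <- roll * pi / 180
  w1 <- -sin(bR); w2 <- cos(bR) * sin(gR); w3 <- cos(bR) * cos(gR)
  sqrt(a^2 * w1^2 + b^2 * w2^2 + c_^2 * w3^2)
}

animal_body <- function(mass = 2.6) build_animal_model(animal_spec(mass))

sphere_body <- function(r = 10, mass = 5) {
  build_ellipsoid_body(ellipsoid_spec(r, r, r, mass))
}

coarse_landscape <- function(body, theta_wing = 0, step = 5, ...) {
  compute_landscape(body, theta_wing, pitch_step = step, ...)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}

# marker track of the animal landmark set under a prescribed rigid motion:
# roll rotation about the body fore-aft axis at roll_rate (rad/s) plus
# lateral translation at v_lat (mm/s); legs folded along the body axis
rigid_track <- function(roll_rate = 0, v_lat = 0, rate = 500, duration = 0.4,
                        model = animal_ke_model()) {
  a <- model$spec$semi_a
  xc <- model$parts$x_cut
  lm <- list(head = c(a, 0, 0), mid = c(xc, 0, 3), abd = c(-a, 0, 0),
             joint_left = c(xc + 12, 0, 0), tip_left = c(xc + 20, 0, 0),
             joint_right = c(xc + 12, 0, 0), tip_right = c(xc + 20, 0, 0))
  t <- seq(0, duration, by = 1 / rate)
  rows <- lapply(names(lm), function(nm) {
    p <- lm[[nm]]
    ang <- roll_rate * t
    tibble::tibble(
      time_s = t, marker = nm,
      x_mm = p[1],
      y_mm = cos(ang) * p[2] - sin(ang) * p[3] + v_lat * t,
      z_mm = sin(ang) * p[2] + cos(ang) * p[3])
  })
  marker_track(dplyr::bind_rows(rows))
}
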