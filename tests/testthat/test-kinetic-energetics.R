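test_that("marker tracks are validated", {
  tr <- rigid_track()
  expect_s3_class(tr, "marker_track")
  gappy <- tr[-5, ]
  expect_error(marker_track(gappy), class = "selfright_gap_error")
  uneven <- dplyr::mutate(tr, time_s = time_s^1.01)
  expect_error(marker_track(uneven), class = "selfright_invalid_track")
})

test_that("zero-phase filtering passes DC and low bands, kills high bands", {
  rate <- 2000
  t <- seq(0, 1, by = 1 / rate)
  base <- rigid_track(rate = rate, duration = 1)
  expect_error(filter_track(base, cutoff = 1200),
               class = "selfright_parameter_error")

  mk_sine <- function(freq) {
    tr <- base
    sel <- tr$marker == "mid"
    tr$y_mm[sel] <- tr$y_mm[sel] + 5 * sin(2 * pi * freq * tr$time_s[sel])
    marker_track(tr)
  }
  amp_after <- function(freq) {
    f <- filter_track(mk_sine(freq), cutoff = 25, order = 6)
    y <- f$y_mm[f$marker == "mid"]
    core <- y[200:(length(y) - 200)]
    (max(core) - min(core)) / 2
  }
  # constant coordinates pass through unchanged
  fc <- filter_track(base, cutoff = 25)
  expect_lt(max(abs(fc$z_mm[fc$marker == "mid"] - 3)), 1e-6)
  expect_lt(amp_after(100) / 5, 0.05)      # > 95% attenuation at 100 Hz
  expect_gt(amp_after(1) / 5, 0.99)        # passband preserved within 1%
})

test_that("static and rigidly translating bodies give the expected states", {
  st0 <- animal_segment_states(rigid_track(0, 0))
  expect_lt(max(abs(c(st0$vx, st0$vy, st0$wx, st0$wy))), 1e-9)
  e0 <- ke_pitch_roll(st0)
  expect_true(all(e0$ke_pitch_mJ == 0) && all(e0$ke_roll_mJ == 0))

  v <- 80
  stv <- animal_segment_states(rigid_track(0, v_lat = v))
  mid <- stv[stv$time_s > 0.05 & stv$time_s < 0.35, ]
  expect_lt(max(abs(mid$vy - v)), 1e-6)
  expect_lt(max(abs(mid$vx)), 1e-6)
  expect_lt(max(abs(c(mid$wx, mid$wy))), 1e-9)
})

test_that("segment energy follows the decomposition formulas", {
  # a point sphere moving laterally: KE_roll = 1/2 m v_y^2, KE_pitch = 0
  states <- tibble::tibble(
    time_s = 0, object = "sphere", type = "sphere", m = 0.14,
    Ixx = 0, Iyy = 0, wx = 0, wy = 0, vx = 0, vy = 100)
  e <- ke_pitch_roll(states)
  expect_equal(e$ke_roll_mJ, 7.0e-4, tolerance = 1e-12)
  expect_equal(e$ke_pitch_mJ, 0)

  # a rod pivoting about one end about the lateral axis:
  # 1/2 (m L^2/12) w^2 + 1/2 m (w L/2)^2 = m L^2 w^2 / 6
  m <- 0.07; L <- 12; w <- 30
  rod <- tibble::tibble(
    time_s = 0, object = "rod", type = "segment", m = m,
    Ixx = 0, Iyy = m * L^2 / 12, wx = 0, wy = w, vx = w * L / 2, vy = 0)
  er <- ke_pitch_roll(rod)
  expect_equal(er$ke_pitch_mJ, m * L^2 * w^2 / 6 * 1e-6, tolerance = 1e-12)
})

test_that("frozen-joint segment sums equal the rigid-body closed form", {
  model <- animal_ke_model()
  w <- 12
  st <- animal_segment_states(rigid_track(roll_rate = w), model)
  e <- ke_pitch_roll(st)
  mid <- e[e$time_s > 0.05 & e$time_s < 0.35, ]
  m <- model$spec$mass
  I_roll <- m * (model$spec$semi_b^2 + model$spec$semi_c^2) / 5
  oracle <- 0.5 * I_roll * w^2 * 1e-6
  expect_rel(mean(mid$ke_roll_mJ), oracle, 0.01)
})

test_that("a constant yaw rotation of the lab frame leaves KE unchanged", {
  sp <- synth_spec(duration = 0.3, seed = 7)
  mt <- gen_marker_tracks(sp)
  e1 <- ke_pitch_roll(animal_segment_states(filter_track(mt$track), mt$model))
  ang <- 30 * pi / 180
  rot <- dplyr::mutate(mt$track,
    x2 = cos(ang) * x_mm - sin(ang) * y_mm,
    y2 = sin(ang) * x_mm + cos(ang) * y_mm,
    x_mm = x2, y_mm = y2)
  rot <- marker_track(rot[, c("time_s", "marker", "x_mm", "y_mm", "z_mm")])
  e2 <- ke_pitch_roll(animal_segment_states(filter_track(rot), mt$model))
  expect_rel(e1$ke_roll_mJ + 1e-12, e2$ke_roll_mJ + 1e-12, 1e-6)
})

test_that("generator ground-truth energy is recovered from noisy tracks", {
  for (sphere in c(0, 0.14)) {
    sp <- synth_spec(duration = 0.5, noise_sd = 0.1, sphere_mass = sphere)
    mt <- gen_marker_tracks(sp)
    e <- ke_pitch_roll(animal_segment_states(filter_track(mt$track), mt$model))
    w <- c(0.05, 0.45)
    expect_rel(average_ke(e, w)[["roll"]],
               average_ke(mt$truth, w)[["roll"]], 0.05)
  }
})

test_that("time averages behave on constants, sinusoids and bad windows", {
  t <- seq(0, 1, by = 1e-3)
  const <- structure(tibble::tibble(time_s = t, ke_pitch_mJ = 3, ke_roll_mJ = 5),
                     class = c("energy_trace", "tbl_df", "tbl", "data.frame"))
  expect_equal(unname(average_ke(const)), c(3, 5))
  # sinusoid over whole periods averages to its mean
  sine <- const
  sine$ke_roll_mJ <- 2 + sin(2 * pi * 5 * t)
  expect_equal(average_ke(sine, c(0, 1 - 1e-3))[["roll"]], 2, tolerance = 1e-6)
  expect_error(average_ke(const, c(2, 3)), class = "selfright_domain_error")
})

test_that("kinetic energy minus barrier has the right sign structure", {
  body <- build_robot_model()
  curves <- barriers_vs_wing_opening(body, c(0, 45, 90), pitch_step = 5,
                                     psi_step = 15)
  t <- seq(0, 1, by = 0.01)
  wing <- tibble::tibble(time_s = t,
                         theta_wing_deg = 90 * sin(pi * pmin(t, 0.5) / 0.5)^2)
  zero <- structure(tibble::tibble(time_s = t, ke_pitch_mJ = 0, ke_roll_mJ = 0),
                    class = c("energy_trace", "tbl_df", "tbl", "data.frame"))
  s0 <- ke_minus_barrier(zero, curves, wing)
  expect_true(all(s0$surplus_pitch_mJ < 0))
  expect_true(all(s0$surplus_roll_mJ < 0))

  # energy pinned at the barrier level gives zero surplus
  at_bar <- zero
  th <- wing$theta_wing_deg
  at_bar$ke_pitch_mJ <- barrier_at(curves, th, "pitch")
  at_bar$ke_roll_mJ <- barrier_at(curves, th, "roll")
  sb <- ke_minus_barrier(at_bar, curves, wing)
  expect_lt(max(abs(c(sb$surplus_pitch_mJ, sb$surplus_roll_mJ))), 1e-9)
  expect_equal(unname(attr(sb, "max_surplus")), c(0, 0), tolerance = 1e-9)

  # a roll energy exceeding the barrier by 20% yields a ~20% surplus
  sur <- at_bar
  sur$ke_roll_mJ <- 1.2 * sur$ke_roll_mJ
  ss <- ke_minus_barrier(sur, curves, wing)
  # the fully-open window spans wing angles within 1% of the plateau, where
  # the barrier still varies slightly
  open_bar <- barrier_at(curves, max(th), "roll")
  expect_rel(attr(ss, "max_surplus")[["roll"]], 0.2 * open_bar, 0.05)

  short <- tibble::tibble(time_s = c(0, 0.1), theta_wing_deg = 0)
  expect_error(ke_minus_barrier(zero, curves, short),
               class = "selfright_alignment_error")
})
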