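test_that("generators are fully deterministic under a fixed seed", {
  sp <- synth_spec(duration = 0.1, seed = 11)
  expect_identical(gen_marker_tracks(sp)$track, gen_marker_tracks(sp)$track)
  o1 <- gen_orientation_trace(sp, "fail")
  o2 <- gen_orientation_trace(sp, "fail")
  expect_identical(o1$trace, o2$trace)
  expect_identical(o1$wing, o2$wing)
})

test_that("null motion produces a static track with zero true energy", {
  sp <- synth_spec(duration = 0.1, leg_amplitude = 0, noise_sd = 0)
  mt <- gen_marker_tracks(sp)
  expect_true(all(mt$truth$ke_roll_mJ == 0) && all(mt$truth$ke_pitch_mJ == 0))
  spread <- mt$track |>
    dplyr::group_by(marker) |>
    dplyr::summarise(s = max(x_mm) - min(x_mm) + max(y_mm) - min(y_mm) +
                       max(z_mm) - min(z_mm))
  expect_lt(max(spread$s), 1e-12)
})

test_that("the tip-sphere ground truth equals 1/2 m v^2 of the tip motion", {
  sp0 <- synth_spec(duration = 0.2, noise_sd = 0)
  sp1 <- synth_spec(duration = 0.2, noise_sd = 0, sphere_mass = 0.14)
  t0 <- gen_marker_tracks(sp0); t1 <- gen_marker_tracks(sp1)
  sphere_truth <- t1$truth$ke_roll_mJ - t0$truth$ke_roll_mJ
  # oracle: numerically differentiate the noiseless tip marker
  tip <- t1$track[t1$track$marker == "tip_left", ]
  vy <- c(NA, diff(tip$y_mm)) * sp1$rate
  both <- 0.5 * 0.14 * vy^2 * 1e-6
  # the right leg is phase-shifted; compare against the summed oracle
  tipr <- t1$track[t1$track$marker == "tip_right", ]
  vyr <- c(NA, diff(tipr$y_mm)) * sp1$rate
  both <- both + 0.5 * 0.14 * vyr^2 * 1e-6
  keep <- seq(10, length(vy) - 10)
  expect_rel(mean(sphere_truth[keep]), mean(both[keep], na.rm = TRUE), 0.02)
})

test_that("orientation traces end in the prescribed basin", {
  sp <- synth_spec(duration = 0.1, seed = 3)
  fail <- gen_orientation_trace(sp, "fail")
  last <- nrow(fail$trace)
  expect_lt(abs(fail$trace$pitch_deg[last]), 5)
  expect_lt(abs(fail$trace$roll_deg[last]), 5)
  expect_equal(max(fail$wing$theta_wing_deg), sp$wing_amplitude)

  roll <- gen_orientation_trace(sp, "roll-success")
  expect_lt(abs(abs(roll$trace$roll_deg[nrow(roll$trace)]) - 180), 5)
  pitch <- gen_orientation_trace(sp, "pitch-success")
  expect_lt(abs(pitch$trace$pitch_deg[nrow(pitch$trace)] - 180), 5)
})

test_that("failed attempts stay inside the upside-down/metastable basin", {
  sp <- synth_spec(seed = 5)
  fail <- gen_orientation_trace(sp, "fail")
  body <- animal_body()
  thetas <- seq(0, 72, by = 12)
  grids <- lapply(thetas, function(th) coarse_landscape(body, th, step = 5))
  tr <- align_wing_profile(fail$trace, fail$wing)
  proj <- project_trajectory(grids, tr)
  gi <- vapply(proj$theta_wing_deg, function(th) which.min(abs(thetas - th)), 1L)
  basins <- vapply(seq_len(nrow(proj)), function(k) {
    basin_of(grids[[gi[k]]], proj$pitch_deg[k], proj$roll_deg[k])
  }, character(1))
  expect_true(all(basins == "upside-down/metastable"))
})

test_that("attempt ensembles respond to energy scale as expected", {
  body <- build_robot_model()
  curves <- barriers_vs_wing_opening(body, seq(0, 90, by = 10),
                                     pitch_step = 2, psi_step = 3)
  bar <- barrier_at(curves, 72, "roll")

  # mean energy ten times the barrier, tiny variance: always first-attempt
  dominant <- simulate_attempts(curves, 72, 30, ke_coef = 10 * bar / 900,
                                cv = 0.01, n = 200, seed = 2)
  expect_equal(dominant$probability, 1)
  expect_true(all(dominant$attempts_to_success$attempts == 1))

  # zero energy never self-rights
  null <- simulate_attempts(curves, 72, 0, n = 100, seed = 2, max_attempts = 10)
  expect_equal(null$probability, 0)
  expect_true(all(!null$attempts_to_success$righted))

  # mean at the barrier: per-attempt success probability ~ 1/2
  at_bar <- simulate_attempts(curves, 72, 30, ke_coef = bar / 900, cv = 0.3,
                              n = 4000, seed = 2, max_attempts = 3)
  expect_lt(abs(at_bar$probability - 0.5), 0.03)
  expect_true(all(at_bar$attempts$ke_roll_mJ >= 0))

  expect_error(simulate_attempts(curves, 95, 30),
               class = "selfright_config_error")
})

test_that("self-righting probability grows with both amplitudes", {
  body <- build_robot_model()
  curves <- barriers_vs_wing_opening(body, seq(0, 90, by = 10),
                                     pitch_step = 2, psi_step = 3)
  wings <- c(60, 72, 83)
  legs <- c(0, 15, 30, 45)
  res <- purrr::map_dfr(wings, function(tw) {
    purrr::map_dfr(legs, function(tl) {
      glance(simulate_attempts(curves, tw, tl, n = 1000,
                               seed = 17 + tw, max_attempts = 25))
    })
  })
  for (tw in wings) {
    sub <- res[res$theta_wing_deg == tw, ]
    expect_true(all(diff(sub$probability) >= 0))
    expect_true(all(diff(sub$mean_attempts) <= 0))
  }
  # non-decreasing in wing opening at fixed large leg amplitude
  at45 <- res[res$theta_leg_deg == 45, ]
  expect_true(all(diff(at45$probability) >= 0))
})
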