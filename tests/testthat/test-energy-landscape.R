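test_that("support heights match the closed-form ellipsoid oracle", {
  body <- animal_body()
  cfg <- configuration()
  # spot values
  expect_equal(com_height(body, cfg, 0, 0), 4, tolerance = 1e-9)
  expect_equal(com_height(body, cfg, 90, 0), 26.5, tolerance = 1e-9)
  expect_equal(com_height(body, cfg, 0, 90), 11.5, tolerance = 1e-9)
  expect_equal(com_height(body, cfg, 45, 0),
               sqrt(26.5^2 / 2 + 4^2 / 2), tolerance = 1e-9)
  # all grid nodes, < 0.5%
  g <- expand.grid(pitch = seq(-180, 180, by = 5), roll = seq(-180, 180, by = 5))
  h <- com_height(body, cfg, g$pitch, g$roll)
  oracle <- ellipsoid_support(26.5, 11.5, 4, g$pitch, g$roll)
  expect_lt(max(abs(h - oracle) / oracle), 0.005)
})

test_that("potential energy is m g z in mJ", {
  body <- animal_body()
  expect_equal(potential_energy(body, 0), 0)
  expect_equal(potential_energy(body, 4), 2.6 * G * 4 * MJ, tolerance = 1e-12)
  heavy <- animal_body(mass = 5.2)
  expect_equal(potential_energy(heavy, 7), 2 * potential_energy(body, 7))
  expect_error(potential_energy(body, -1), class = "selfright_domain_error")
})

test_that("landscape grids respect symmetry, wrapping and bounds", {
  expect_error(compute_landscape(animal_body(), 0, pitch_step = 7),
               class = "selfright_domain_error")
  g <- coarse_landscape(animal_body(), 0, step = 5)
  E <- g$energy
  nr <- length(g$roll)
  # mirror symmetry in roll for a laterally symmetric body
  expect_lt(max(abs(E - E[, nr:1])), 1e-9)
  # wrap consistency: roll -180 and +180 are the same orientation
  expect_lt(max(abs(E[, 1] - E[, nr])), 1e-12)
  # global minimum at the upside-down node
  idx <- which(E == min(E), arr.ind = TRUE)
  expect_true(any(g$pitch[idx[, 1]] == 0 & g$roll[idx[, 2]] == 0))
  # roll = 0 row peaks at m g a at pitch = +-90
  r0 <- E[, g$roll == 0]
  expect_equal(max(r0), 2.6 * G * 26.5 * MJ, tolerance = 1e-9)
  expect_setequal(g$pitch[which(r0 == max(r0))], c(-90, 90))
  # energy bounds
  expect_gte(min(E), 2.6 * G * 4 * MJ - 1e-12)
  expect_lte(max(E), 2.6 * G * 26.5 * MJ + 1e-12)
})

test_that("minima are located and classified on the wrapped grid", {
  g <- coarse_landscape(animal_body(), 0, step = 5)
  mins <- find_minima(g)
  expect_equal(nrow(mins), 4L)
  expect_setequal(mins$basin,
                  c("upside-down/metastable", "pitch-upright",
                    "roll-upright-left", "roll-upright-right"))
  expect_true(all(!mins$plateau))
  expect_equal(mins$pitch[mins$basin == "pitch-upright"], 180)
  expect_setequal(mins$roll[grepl("roll-upright", mins$basin)], c(-180, 180))

  # degenerate constant landscape: a sphere has no strict minima
  gs <- coarse_landscape(sphere_body(), 0, step = 15)
  ms <- find_minima(gs)
  expect_true(all(ms$plateau))
  expect_equal(nrow(ms), 1L)
})

test_that("a robot-like composite gains a backward-pitch minimum", {
  g <- compute_landscape(build_robot_model(), 0, pitch_step = 2)
  mins <- find_minima(g)
  backward <- mins[mins$basin == "backward", ]
  expect_gt(nrow(backward), 0)
  expect_true(any(backward$pitch >= -180 & backward$pitch < -162))
})

test_that("the tracked metastable minimum rises in pitch as wings open", {
  body <- build_robot_model()
  tr <- track_metastable(body, c(0, 20, 40, 60, 72, 83), pitch_step = 2)
  expect_equal(tr$pitch[1], 0)
  expect_true(all(diff(tr$pitch) > 0))
  # zero roll within grid resolution while the triangular support is wide;
  # near-vertical wings flatten the basin bottom laterally and the minimum
  # may sit a few degrees off-axis (symmetrically paired)
  expect_true(all(abs(tr$roll[tr$theta_wing <= 60]) <= 2))
  expect_true(all(abs(tr$roll) <= 15))

  ta <- track_metastable(animal_body(), c(0, 30, 60), pitch_step = 5)
  expect_true(all(diff(ta$pitch) >= 0))
  expect_true(all(abs(ta$roll) <= 5))
})

test_that("trajectories project onto the evolving landscape", {
  body <- animal_body()
  grids <- list(coarse_landscape(body, 0, step = 5))
  static <- tibble::tibble(time_s = seq(0, 0.05, by = 0.01),
                           pitch_deg = 0, roll_deg = 0, theta_wing_deg = 0)
  pr <- project_trajectory(grids, static)
  expect_equal(pr$energy_mJ, rep(2.6 * G * 4 * MJ, nrow(pr)), tolerance = 1e-9)

  ends <- tibble::tibble(time_s = c(0, 0.01), pitch_deg = c(0, 0),
                         roll_deg = c(20, 180), theta_wing_deg = 0)
  pe <- project_trajectory(grids, ends)
  expect_match(attr(pe, "final_basin"), "roll-upright")

  # out-of-range angles are wrapped with a warning
  oow <- tibble::tibble(time_s = 0, pitch_deg = 190, roll_deg = 0,
                        theta_wing_deg = 0)
  expect_warning(project_trajectory(grids, oow), "wrap")

  # a successful synthetic roll crosses the barrier: energy rises to an
  # interior maximum and falls into the roll basin
  roll_tr <- tibble::tibble(
    time_s = seq(0, 1, by = 0.01),
    pitch_deg = 0,
    roll_deg = seq(0, 180, length.out = 101),
    theta_wing_deg = 0)
  pb <- project_trajectory(grids, roll_tr)
  k <- which.max(pb$energy_mJ)
  expect_gt(k, 1); expect_lt(k, nrow(pb))
  expect_lt(pb$energy_mJ[1], pb$energy_mJ[k])
  expect_lt(pb$energy_mJ[nrow(pb)], pb$energy_mJ[k])
})

test_that("uneven ground makes the landscape more rugged", {
  body <- animal_body()
  flat <- coarse_landscape(body, 0, step = 10)
  rough <- compute_landscape(body, 0, pitch_step = 10,
                             ground = sinusoidal_ground(10, 40, extent = 120,
                                                        n = 97))
  expect_gt(nrow(find_minima(rough)), nrow(find_minima(flat)))
})

test_that("empty bodies are rejected", {
  expect_error(com_height(structure(list(parts = list()),
                                    class = "articulated_body")),
               class = "selfright_invalid_model")
})
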