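test_that("part construction validates shapes and masses", {
  expect_error(part_shape("ellipsoid", list(a = -1, b = 1, c = 1), 1),
               class = "selfright_invalid_shape")
  expect_error(part_shape("rod", list(), 1), class = "selfright_invalid_shape")
  expect_error(part_shape("cuboid", list(lx = 1, ly = 1, lz = 1), -0.1),
               class = "selfright_invalid_shape")
  expect_error(ellipsoid_spec(26.5, 11.5, 4, 0), class = "selfright_invalid_shape")
  expect_error(build_animal_model(wing_cut_height = 1.2),
               class = "selfright_invalid_geometry")
})

test_that("discretization preserves mass and respects shape", {
  # degenerate point mass: a single point at the center
  pt <- discretize_part(part_shape("point", mass = 0.14), 100)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$mass, 0.14)
  expect_equal(c(pt$x, pt$y, pt$z), c(0, 0, 0))

  parts <- list(
    part_shape("ellipsoid", list(a = 26.5, b = 11.5, c = 4), 2.6),
    part_shape("cuboid", list(lx = 36, ly = 27, lz = 24), 28.6),
    part_shape("rod", list(length = 100), 4.3),
    part_shape("shell_slice", list(a = 130, b = 110, c = 21.5), 28.7,
               constraints = data.frame(axis = c(3, 2), dir = c(-1, 1),
                                        bound = c(0, 0))))
  for (p in parts) {
    cl <- discretize_part(p, 500)
    expect_lt(abs(sum(cl$mass) - p$mass) / p$mass, 1e-9)
  }

  # ellipsoid cloud: center of mass within 1% of semi-axis c of the center
  cl <- discretize_part(parts[[1]], 2000)
  com <- colSums(cl[, c("x", "y", "z")] * cl$mass) / sum(cl$mass)
  expect_lt(max(abs(com)), 0.01 * 4)

  # ellipsoid points inside the surface; rod on its segment
  expect_true(all((cl$x / 26.5)^2 + (cl$y / 11.5)^2 + (cl$z / 4)^2 <= 1 + 1e-12))
  rod <- discretize_part(parts[[3]], 50)
  expect_true(all(abs(rod$x) <= 50) && all(rod$y == 0) && all(rod$z == 0))

  # deterministic for a fixed quasi-random sequence
  expect_identical(discretize_part(parts[[4]], 400),
                   discretize_part(parts[[4]], 400))
})

test_that("cuboid cloud reproduces the closed-form centroidal inertia", {
  m <- 2.0; w <- 30; h <- 20; d <- 10
  cl <- discretize_part(part_shape("cuboid", list(lx = w, ly = h, lz = d), m),
                        4000)
  Ixx <- sum(cl$mass * (cl$y^2 + cl$z^2))
  expect_rel(Ixx, m * (h^2 + d^2) / 12, 0.02)
  Iyy <- sum(cl$mass * (cl$x^2 + cl$z^2))
  expect_rel(Iyy, m * (w^2 + d^2) / 12, 0.02)
})

test_that("point clouds converge: doubling resolution barely moves the CoM", {
  com_at <- function(p, n) {
    cl <- discretize_part(p, n)
    colSums(cl[, c("x", "y", "z")] * cl$mass) / sum(cl$mass)
  }
  ell <- part_shape("ellipsoid", list(a = 26.5, b = 11.5, c = 4), 2.6)
  expect_lt(sqrt(sum((com_at(ell, 4000) - com_at(ell, 2000))^2)), 0.005 * 4)
  # non-symmetric surface region: the dorsal half-shell
  sl <- part_shape("shell_slice", list(a = 26.5, b = 11.5, c = 4), 1,
                   constraints = data.frame(axis = 3, dir = -1, bound = 0))
  expect_lt(sqrt(sum((com_at(sl, 4000) - com_at(sl, 2000))^2)), 0.005 * 4)
})

test_that("posing is rigid and matches explicit Z-Y'-X' rotation matrices", {
  body <- animal_body()
  cfg <- configuration(40, 0)
  cloud0 <- pose_points(body, cfg, c(yaw = 0, pitch = 0, roll = 0), 200)
  posed <- pose_points(body, cfg, c(yaw = 30, pitch = 40, roll = 50), 200)

  # independent oracle: single-axis matrices written out and multiplied in
  # the intrinsic Z-Y'-X' order
  cs <- function(d) c(cos(d * pi / 180), sin(d * pi / 180))
  zc <- cs(30); yc <- cs(40); xc <- cs(50)
  Rz <- rbind(c(zc[1], -zc[2], 0), c(zc[2], zc[1], 0), c(0, 0, 1))
  Ry <- rbind(c(yc[1], 0, yc[2]), c(0, 1, 0), c(-yc[2], 0, yc[1]))
  Rx <- rbind(c(1, 0, 0), c(0, xc[1], -xc[2]), c(0, xc[2], xc[1]))
  expected <- as.matrix(cloud0[, c("x", "y", "z")]) %*% t(Rz %*% Ry %*% Rx)
  expect_lt(max(abs(as.matrix(posed[, c("x", "y", "z")]) - expected)), 1e-9)

  # identity pose returns the body-frame cloud
  expect_equal(pose_points(body, cfg, c(yaw = 0, pitch = 0, roll = 0), 200),
               cloud0)

  # a half-turn in pitch inverts the dorsoventral axis
  flipped <- pose_points(body, cfg, c(yaw = 0, pitch = 180, roll = 0), 200)
  expect_lt(max(abs(flipped$z + cloud0$z)), 1e-9)

  # rigid transform: pairwise distances preserved to 1e-9 relative
  i <- seq(1, nrow(cloud0), by = 37)
  d0 <- dist(cloud0[i, c("x", "y", "z")])
  d1 <- dist(posed[i, c("x", "y", "z")])
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1)), 1e-9)

  # mass conservation through posing
  expect_lt(abs(sum(posed$mass) - body$total_mass) / body$total_mass, 1e-9)
})

test_that("default models stay bilaterally symmetric under wing opening", {
  body <- build_robot_model()
  for (th in c(0, 40)) {
    cloud <- pose_points(body, configuration(th, 0), resolution = 300)
    left <- as.matrix(cloud[cloud$role == "wing_left", c("x", "y", "z")])
    right <- as.matrix(cloud[cloud$role == "wing_right", c("x", "y", "z")])
    mirrored <- left %*% diag(c(1, -1, 1))
    # set distance below the discretization spacing
    spacing <- 2 * sqrt(2 * pi * 130 * 110 / 2 / nrow(left))
    nn <- apply(mirrored, 1, function(p) {
      min(sqrt(colSums((t(right) - p)^2)))
    })
    expect_lt(stats::median(nn), spacing)
    # mirrored mass centroids agree
    ml <- cloud$mass[cloud$role == "wing_left"]
    mr <- cloud$mass[cloud$role == "wing_right"]
    expect_lt(max(abs(colSums(mirrored * ml) / sum(ml) -
                      colSums(right * mr) / sum(mr))), 1.5)
  }
})

test_that("animal model: closed wings give exactly the full ellipsoid surface", {
  body <- animal_body()
  probe <- expand.grid(pitch = seq(-180, 180, by = 30),
                       roll = seq(-180, 180, by = 30))
  h <- com_height(body, configuration(0, 0), probe$pitch, probe$roll)
  expect_lt(max(abs(h - ellipsoid_support(26.5, 11.5, 4, probe$pitch,
                                          probe$roll))), 1e-9)
})

test_that("robot composite masses follow the build table", {
  body <- build_robot_model()
  expect_equal(body$total_mass, 260, tolerance = 1e-12)
  pm <- robot_part_masses()
  expect_error(build_robot_model(part_masses = pm[-1]),
               class = "selfright_config_error")
})

test_that("a symmetric closed shell with massless fittings has a central CoM", {
  shell <- part_shape("shell_slice", list(a = 130, b = 110, c = 21.5), 70.8)
  body <- articulated_body(list(shell), name = "closed_shell")
  expect_lt(max(abs(selfright:::body_com(body))), 0.5)
})
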