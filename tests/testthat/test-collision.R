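# Contact detection, the unilateral solver, grasping and snap-in.

test_that("point-vs-SDF contacts report depth and normal correctly", {
  # half-space: a deep box whose top face is the plane z = 0
  plane <- sdf_shape("box", half_extents = c(10, 10, 1))
  ppose <- rigid_pose(c(0, 0, -1))
  cts <- sdf_point_contacts(rbind(c(0.3, -0.2, -0.1)), plane, margin = 0,
                            pose = ppose)
  expect_length(cts, 1)
  expect_equal(cts[[1]]$depth, 0.1, tolerance = 1e-9)
  expect_equal(cts[[1]]$normal, c(0, 0, 1), tolerance = 1e-6)
  # separated point: no contact
  expect_length(sdf_point_contacts(rbind(c(0, 0, 0.5)), plane, 0, pose = ppose), 0)
  # random points against a sphere: analytic depth and normal
  set.seed(5)
  sph <- sdf_shape("sphere", radius = 0.8)
  P <- matrix(rnorm(60), 20, 3)
  P <- P / sqrt(rowSums(P^2)) * runif(20, 0.2, 1.2)
  cts <- sdf_point_contacts(P, sph, margin = 0.05)
  d <- sqrt(rowSums(P^2))
  hit <- which(d - 0.8 < 0.05)
  expect_length(cts, length(hit))
  for (i in seq_along(cts)) {
    p <- cts[[i]]$point
    expect_equal(cts[[i]]$depth, 0.05 - (sqrt(sum(p^2)) - 0.8), tolerance = 1e-6)
    expect_equal(cts[[i]]$normal, p / sqrt(sum(p^2)), tolerance = 1e-6)
  }
  expect_error(sdf_point_contacts(P, sph, margin = -1), "margin")
  # grid SDF: points outside the domain are treated as no contact
  g <- sdf_grid(c(0, 0, 0), 0.1, c(5, 5, 5))
  expect_length(sdf_point_contacts(rbind(c(-5, -5, -5)), g, margin = 1), 0)
})

test_that("feature sampling finds the deepest contact of an edge or triangle", {
  plane <- sdf_shape("box", half_extents = c(10, 10, 1))
  ppose <- rigid_pose(c(0, 0, -1))
  # edge fully outside
  e <- list(kind = "edge", vertices = rbind(c(0, 0, 1), c(1, 0, 2)))
  expect_length(sample_feature_contacts(e, plane, 8, 0, ppose), 0)
  # edge crossing the plane: deepest sample near the true deepest endpoint
  e2 <- list(kind = "edge", vertices = rbind(c(0, 0, 0.5), c(1, 0, -0.3)))
  cs <- sample_feature_contacts(e2, plane, 64, 0, ppose)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$depth, 0.3, tolerance = 0.8 / 63 + 1e-9)
  # triangle tangent to a sphere: at most one contact, depth ~ 0
  sph <- sdf_shape("sphere", radius = 0.5)
  tri <- list(kind = "triangle",
              vertices = rbind(c(0, 0, 0.5), c(1, 1, 1.5), c(-1, 1, 1.5)))
  cs2 <- sample_feature_contacts(tri, sph, 16, 1e-9)
  expect_lte(length(cs2), 1)
  if (length(cs2) == 1) expect_lt(cs2[[1]]$depth, 1e-6)
  expect_error(sample_feature_contacts(list(kind = "edge",
                                            vertices = rbind(0, 1)), sph, 1),
               ">= 2 samples")
})

test_that("the unilateral solver reproduces the inelastic impact impulse", {
  m <- 3.7e-3
  sys <- system_matrices(rep(m, 3), matrix(0, 3, 3))
  st <- mech_state(c(0, 0, 0), c(0, 0, -0.25))
  # empty contact set: zero impulses
  z <- solve_contacts(sys, st, list(), 0.04)
  expect_identical(z$lambda, numeric(0))
  expect_true(all(z$impulses == 0))
  # point mass exactly on a rigid plane, moving down: lambda = m |v|
  ct <- contact(c(0, 0, 0), c(0, 0, 1), 0, node = 1L)
  sol <- solve_contacts(sys, st, list(ct), 0.04)
  expect_equal(sol$lambda, m * 0.25, tolerance = 1e-8)
  st2 <- backward_euler_step(st, sys, impulses = sol$impulses,
                             settings = solver_settings(time_step = 0.04))
  expect_lt(abs(st2$v[3]), 1e-12)             # post-impact normal velocity 0
  expect_lt(sol$residual, 1e-10)
  # separating contact: no impulse, no attraction
  st_up <- mech_state(c(0, 0, 0), c(0, 0, +0.25))
  sol_up <- solve_contacts(sys, st_up, list(ct), 0.04)
  expect_equal(sol_up$lambda, 0)
  expect_true(all(sol_up$lambda >= 0))
})

test_that("grasp spring force is zero at coincidence, linear, and reaches F/k", {
  att <- grasp_attachment(1L, rbind(c(0, 0, 0)), stiffness = 50, damping = 0)
  st <- mech_state(c(0, 0, 0))
  expect_equal(grasp_spring_force(att, rigid_pose(), st), rbind(c(0, 0, 0)))
  st1 <- mech_state(c(1e-3, 0, 0))
  st2 <- mech_state(c(2e-3, 0, 0))
  f1 <- grasp_spring_force(att, rigid_pose(), st1)
  expect_equal(grasp_spring_force(att, rigid_pose(), st2), 2 * f1)
  expect_equal(f1[1, 1], -50 * 1e-3)
  # static equilibrium under constant load: offset = |F| / k
  m <- 1e-4; k <- 80; Fx <- 0.02
  sys <- system_matrices(rep(m, 3), diag(k, 3), diag(2 * sqrt(k * m), 3))
  st <- mech_state(c(0, 0, 0))
  for (i in 1:4000) st <- backward_euler_step(st, sys, f_ext = c(Fx, 0, 0),
                                              settings = solver_settings(time_step = 0.04))
  expect_equal(st$x[1], Fx / k, tolerance = 1e-6)
})

test_that("snap-in engagement is geometric and monotone in the threshold", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ring <- cbind(0.3 * cos(th), 0, 0.3 * sin(th))
  a <- c(0, -1, 0); b <- c(0, 1, 0)
  # separated: the loop centre is far from the axis
  far <- sweep(ring, 2, c(5, 0, 0), "+")
  expect_false(snap_in_state(far, a, b, 0.12e-0)$engaged)
  # fully seated: loop centred on the process
  expect_true(snap_in_state(ring, a, b, 0.12)$engaged)
  # engagement position varies monotonically with the detent threshold
  offsets <- seq(0, 1, by = 0.05)
  engage_at <- vapply(c(0.1, 0.3, 0.6), function(thr) {
    min(offsets[vapply(offsets, function(o) {
      snap_in_state(sweep(ring, 2, c(1 - o, 0, 0), "+"), a, b, thr)$engaged
    }, TRUE)])
  }, 1)
  expect_true(all(diff(engage_at) <= 0))   # larger threshold engages earlier
})

test_that("a grasped prosthesis tracks a slowly moving pose with bounded lag", {
  # quasistatic: lag -> 0 as grasp stiffness -> infinity
  m <- 1e-5
  lag <- vapply(c(100, 1000, 10000), function(k) {
    sys <- system_matrices(rep(m, 3), diag(k, 3), diag(0.01, 3))
    sys$anchors <- list(nodes = 1L, k = k, c = 0, rest = rbind(c(0, 0, 0)))
    st <- mech_state(c(0, 0, 0))
    resist <- 0.001                          # small constant drag (N)
    for (i in 1:200) {
      apos <- rbind(c(i * 1e-5, 0, 0))
      f <- otosim:::anchor_forces(sys, apos) + c(-resist, 0, 0)
      st <- backward_euler_step(st, sys, f_ext = f,
                                settings = solver_settings(time_step = 0.04))
    }
    2e-3 - st$x[1]
  }, 1)
  expect_true(all(diff(lag) < 0))
})
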