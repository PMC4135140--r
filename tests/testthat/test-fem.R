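# Element stiffness, assembly, damping and the implicit integrator.

test_that("tetrahedral stiffness matches the independent energy oracle", {
  set.seed(1)
  for (rep in 1:3) {
    coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) +
      matrix(runif(12, -0.1, 0.1), 4, 3)
    if (det(t(coords[2:4, ]) - coords[1, ]) <= 0) coords <- coords[c(1, 3, 2, 4), ]
    E <- 1.7e6; nu <- 0.3
    K <- tet_element_stiffness(coords, E, nu)
    expect_equal(K, t(K), tolerance = 1e-14)
    # rigid translation produces no force
    for (ax in 1:3) {
      u <- rep(0, 12); u[seq(ax, 12, by = 3)] <- 1
      expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
    }
    # exactly six zero-energy modes
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
    Ko <- energy_hessian(function(u) tet_strain_energy(coords, E, nu, u), 12)
    expect_lt(max(abs(K - Ko)), 1e-10 * max(abs(Ko)))
  }
  expect_error(tet_element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0, 1, 0), c(1, 1, 0)), 1e6, 0.3),
               "degenerate")
})

test_that("CST membrane stiffness matches the plane-stress oracle", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  E <- 3.2e7; nu <- 0.3; th <- 7.4e-5
  K <- cst_membrane_stiffness(coords, E, nu, th)
  expect_equal(K, t(K), tolerance = 1e-14)
  for (ax in 1:3) {
    u <- rep(0, 9); u[seq(ax, 9, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
  }
  # thickness scales the stiffness linearly, entrywise
  expect_equal(cst_membrane_stiffness(coords, E, nu, 2 * th), 2 * K,
               tolerance = 1e-14)
  # independent plane-stress energy oracle, including a tilted triangle
  for (C in list(coords, coords %*% t(otosim:::quat_to_matrix(c(0.9, 0.3, 0.2, 0.1))))) {
    Kc <- cst_membrane_stiffness(C, E, nu, th)
    Ko <- energy_hessian(function(u) cst_strain_energy(C, E, nu, th, u), 9)
    expect_lt(max(abs(Kc - Ko)), 1e-10 * max(abs(Ko)))
  }
  # prescribed uniaxial stretch: nodal force matches the closed form
  eps <- 1e-3
  u <- rep(0, 9); u[4] <- eps          # node 2 moves +x
  f <- as.numeric(K %*% u)
  sigx <- E / (1 - nu^2) * eps          # plane stress, eyy = 0
  # equivalent nodal force on the loaded edge: sig * thickness * edge/2
  expect_equal(f[4], sigx * th * 1 / 2, tolerance = 1e-10)
  # in-plane reduced stiffness has exactly 3 zero modes
  Tb <- matrix(0, 6, 9)
  for (a in 1:3) { Tb[2 * a - 1, 3 * a - 2] <- 1; Tb[2 * a, 3 * a - 1] <- 1 }
  K2 <- Tb %*% K %*% t(Tb)
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 3L)
  expect_error(cst_membrane_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                      E, nu, th), "zero-area")
})

test_that("rayleigh_damping is exactly alpha M + beta K", {
  M <- Matrix::Diagonal(x = c(1, 2, 3))
  K <- Matrix::Matrix(rbind(c(2, -1, 0), c(-1, 2, -1), c(0, -1, 2)))
  expect_equal(as.matrix(rayleigh_damping(M, K, 0, 1e-4)),
               as.matrix(1e-4 * K))
  expect_true(all(as.matrix(rayleigh_damping(M, K, 0, 0)) == 0))
  expect_equal(as.matrix(rayleigh_damping(M, K, 1, 0)), as.matrix(M))
  expect_error(rayleigh_damping(M, K[1:2, 1:2], 1, 1), "shape")
})

test_that("assembly: fixed systems, spring blocks, mass conservation, damping", {
  b <- mini_tet_body()
  sc <- mini_scene(list(solo = b),
                   fixed = data.frame(body = "solo", node = 1:4))
  sys <- assemble_system(sc, corotational = FALSE)
  expect_equal(sys$nfree, 0L)                    # fully constrained -> empty
  # two bodies joined by an axial spring: K block equals the textbook block
  b2 <- mini_tet_body(origin = c(5e-3, 1e-3, 2e-3))
  sc2 <- mini_scene(list(p = mini_tet_body(young = 1e-8),
                         q = within(b2, material <- material(1e-8, 0.3, 1000))),
                    springs = data.frame(body_a = "p", node_a = 2L,
                                         body_b = "q", node_b = 1L,
                                         ax = 0, ay = 0, az = 0,
                                         stiffness = 123, kind = "axial",
                                         rest_length = 0))
  sys2 <- assemble_system(sc2, corotational = FALSE)
  d <- (b2$mesh$nodes[1, ] - c(1e-3, 0, 0))
  d <- d / sqrt(sum(d^2))
  block <- 123 * (d %o% d)
  dofs <- c(3 * 2 - 2 + 0:2, 3 * (4 + 1) - 2 + 0:2)
  Ks <- as.matrix(sys2$K[dofs, dofs])
  expect_equal(Ks, rbind(cbind(block, -block), cbind(-block, block)),
               tolerance = 1e-6)
  # lumped mass conserves total mass exactly
  scene <- default_scene()
  sysf <- assemble_system(scene, corotational = FALSE)
  mass_lumped <- sum(sysf$M) / 3
  mass_true <- sum(vapply(scene$bodies, function(b) {
    v <- switch(b$kind,
      tet = sum(otosim:::tet_signed_volumes(b$mesh$nodes, b$mesh$tetrahedra)),
      hex = sum(otosim:::hex_volumes(b$mesh$nodes, b$mesh$hexahedra)),
      tri = sum(otosim:::tri_areas(b$mesh$nodes, b$mesh$triangles)) *
        b$mesh$thickness)
    v * b$material$density
  }, 1))
  expect_equal(mass_lumped, mass_true, tolerance = 1e-12)
  # C = alpha M + beta K exactly
  expect_lt(max(abs(sysf$C - (0 * Matrix::Diagonal(x = sysf$M) +
                              1e-4 * sysf$K))), 1e-18)
  # global rigid translation produces no elastic force (anchored springs
  # excluded: restrict to a body with no world anchors)
  expect_error(assemble_system(scene, bodies = "nothing_here"), "unknown body")
})

test_that("one backward-Euler step equals the scalar closed form", {
  m <- 2.3; k <- 47; c <- 0.31; dt <- 0.04
  x0 <- 0.12; v0 <- -0.34; fe <- 0.56
  sys <- system_matrices(m, matrix(k, 1, 1), matrix(c, 1, 1))
  st <- backward_euler_step(mech_state(x0, v0), sys, f_ext = fe,
                            settings = solver_settings(time_step = dt))
  dv <- dt * (fe - k * x0 - c * v0 - dt * k * v0) / (m + dt * c + dt^2 * k)
  expect_equal(st$v, v0 + dv, tolerance = 1e-12)
  expect_equal(st$x, x0 + dt * (v0 + dv), tolerance = 1e-12)
  expect_equal(st$time, dt)
})

test_that("equilibrium is a fixed point and damped vibration dissipates", {
  m <- 1e-3; k <- 200
  sys <- system_matrices(m, matrix(k, 1, 1), matrix(0.05, 1, 1))
  st <- backward_euler_step(mech_state(0, 0), sys,
                            settings = solver_settings(time_step = 0.04))
  expect_lt(abs(st$v), 1e-12)
  expect_lt(abs(st$x), 1e-12)
  # free vibration with Rayleigh beta > 0: energy nonincreasing over 100 steps
  for (cc in c(0, 1e-4 * k)) {
    sysd <- system_matrices(m, matrix(k, 1, 1), matrix(cc, 1, 1))
    st <- mech_state(1e-3, 0)
    en <- function(s) 0.5 * m * s$v^2 + 0.5 * k * s$x^2
    e_prev <- en(st)
    ok <- TRUE
    for (i in 1:100) {
      st <- backward_euler_step(st, sysd, settings = solver_settings(time_step = 0.04))
      e <- en(st)
      if (e > e_prev + 1e-15) ok <- FALSE
      e_prev <- e
    }
    expect_true(ok)   # backward Euler never amplifies, for any dt
  }
})

test_that("corotational forces reduce to the linear model for small displacements", {
  b <- mini_tet_body()
  sc <- mini_scene(list(solo = b), fixed = data.frame(body = "solo", node = 1L))
  sys_l <- assemble_system(sc, corotational = FALSE)
  sys_c <- assemble_system(sc, corotational = TRUE)
  set.seed(3)
  du <- rnorm(12)
  err <- vapply(c(1e-4, 1e-5, 1e-6), function(scale) {
    x <- sys_l$x0 + scale * du * 1e-3
    fl <- otosim:::elastic_forces(sys_l, x)$f
    fc <- otosim:::elastic_forces(sys_c, x)$f
    max(abs(fl - fc)) / (max(abs(fl)) + 1e-300)
  }, 1)
  expect_true(all(diff(err) <= 1e-12 + 0 * err[-1]) || all(err < 1e-3))
  expect_lt(err[3], 1e-5)
})
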