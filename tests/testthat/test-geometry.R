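# Mesh containers, procedural anatomy and signed-distance primitives.

test_that("mesh containers enforce their invariants", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- tet_mesh(nodes, matrix(1:4, 1))
  expect_s3_class(m, "tet_mesh")
  # inverted ordering -> negative volume -> rejected
  expect_error(tet_mesh(nodes, matrix(c(1, 3, 2, 4), 1)), "non-positive")
  # flat (degenerate) tetrahedron rejected
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(tet_mesh(flat, matrix(1:4, 1)), "non-positive")
  expect_error(tet_mesh(nodes, rbind(1:4, 1:4)), "duplicate")
  expect_error(tet_mesh(nodes, matrix(c(1, 2, 3, 5), 1)), "out of range")
  expect_error(tri_shell(nodes[1:3, ], matrix(1:3, 1), thickness = -1),
               "thickness")
  expect_error(hex_mesh(nodes, matrix(rep(1:8, 1), 1)), "out of range")
})

test_that("mesh_volume is exact on hexahedra, additive, and guards openness", {
  cube <- box_hex_mesh(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1))
  expect_equal(mesh_volume(cube), 1.0)
  # additivity over disjoint parts
  m1 <- box_hex_mesh(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  m2 <- box_hex_mesh(c(5, 5, 5), c(6, 7, 8), c(2, 2, 2))
  expect_equal(mesh_volume(m1) + mesh_volume(m2), 1 + 1 * 2 * 3,
               tolerance = 1e-12)
  # open surface is rejected
  tri <- tri_shell(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  expect_error(mesh_volume(tri), "not closed")
})

test_that("icosphere volume converges to the analytic sphere volume", {
  r <- 2.5
  s <- icosphere(r, level = 4)
  expect_lt(abs(mesh_volume(s) / (4 / 3 * pi * r^3) - 1), 0.01)
})

test_that("voxel tet meshes are conforming and positively oriented", {
  cells <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  m <- voxel_tet_mesh(cells, 0.5)
  vols <- otosim:::tet_signed_volumes(m$nodes, m$tetrahedra)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 4 * 0.5^3, tolerance = 1e-12)
  # every interior triangular face is shared by exactly two tetrahedra
  f <- rbind(m$tetrahedra[, c(1, 2, 3)], m$tetrahedra[, c(1, 2, 4)],
             m$tetrahedra[, c(1, 3, 4)], m$tetrahedra[, c(2, 3, 4)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true(all(table(key) <= 2))
})

test_that("the default scene has the stated footplate and prosthesis dimensions", {
  scene <- default_scene()
  g <- scene$sdfs$footplate
  xs <- otosim:::sdf_axis(g, 1); ys <- otosim:::sdf_axis(g, 2)
  inside <- g$values < g$spacing / 2       # material within half a voxel
  # elliptic footplate lateral extents 2.8 x 1.52 mm within one voxel
  expect_equal(diff(range(xs[apply(inside, 1, any)])) * 1e3, 2.8,
               tolerance = g$spacing * 1e3 / 2.8)
  expect_equal(diff(range(ys[apply(inside, 2, any)])) * 1e3, 1.52,
               tolerance = g$spacing * 1e3 / 1.52)
  # footplate FEM mesh extents within one cell
  fp <- scene$bodies$footplate$mesh
  expect_lt(abs(diff(range(fp$nodes[, 1])) - 2.8e-3), 0.21e-3)
  expect_lt(abs(diff(range(fp$nodes[, 2])) - 1.52e-3), 0.2e-3)
  # piston shaft: 0.4 mm square section, 4.5 mm long
  sh <- scene$bodies$prosthesis_shaft$mesh
  expect_equal(diff(range(sh$nodes[, 1])) * 1e3, 0.4, tolerance = 1e-9)
  expect_equal(diff(range(sh$nodes[, 3])) * 1e3, 4.5, tolerance = 1e-9)
  # all element volumes/areas strictly positive in every body
  for (b in scene$bodies) {
    ok <- switch(b$kind,
      tet = all(otosim:::tet_signed_volumes(b$mesh$nodes, b$mesh$tetrahedra) > 0),
      hex = all(otosim:::hex_volumes(b$mesh$nodes, b$mesh$hexahedra) > 0),
      tri = all(otosim:::tri_areas(b$mesh$nodes, b$mesh$triangles) > 0))
    expect_true(ok)
  }
  # target point on the footplate lateral surface
  expect_equal(scene$target_point[3], 0)
  expect_equal(scene$speculum_diameter, 6e-3)
})

test_that("build_scene is deterministic and validates its configuration", {
  s1 <- build_scene()
  s2 <- build_scene()
  expect_identical(s1$bodies, s2$bodies)
  expect_identical(s1$sdfs$footplate$values, s2$sdfs$footplate$values)
  bad <- scene_config()
  bad$footplate$thickness <- -1
  expect_error(build_scene(bad), "configuration error")
  expect_error(build_scene(list(nonsense = 1)), "unknown configuration key")
})

test_that("primitive SDFs have the right sign, zero set and eikonal property", {
  grid <- list(origin = c(-1, -1, -1), spacing = 0.05, dims = c(41, 41, 41))
  for (spec in list(
    sdf_shape("sphere", radius = 0.7),
    sdf_shape("ellipsoid", semi_axes = c(0.9, 0.5, 0.35)),
    sdf_shape("capsule", a = c(-0.4, 0, 0), b = c(0.4, 0, 0), radius = 0.3),
    sdf_shape("cylinder", radius = 0.5, half_height = 0.4),
    sdf_shape("box", half_extents = c(0.6, 0.45, 0.3)))) {
    g <- primitive_sdf(spec, grid)
    centre_val <- sdf_eval(spec, rbind(c(0, 0, 0)))
    expect_lt(centre_val, 0)                     # negative strictly inside
    # zero level within half a voxel of the analytic surface for the sphere
    if (spec$kind == "sphere") {
      expect_equal(centre_val, -0.7, tolerance = 1e-12)
      surf <- sdf_eval(spec, rbind(c(0.7, 0, 0), c(0, -0.7, 0)))
      expect_equal(surf, c(0, 0), tolerance = 1e-12)
    }
  }
  # eikonal: |grad| = 1 within 5% at interior points away from the medial axis
  set.seed(42)
  for (spec in list(sdf_shape("sphere", radius = 0.7),
                    sdf_shape("ellipsoid", semi_axes = c(1.4, 0.76, 0.4)),
                    sdf_shape("capsule", a = c(-0.4, 0, 0), b = c(0.4, 0, 0),
                              radius = 0.3))) {
    dirs <- matrix(rnorm(60), 20, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    # points at 80-95% of the way to the surface along random directions
    pts <- t(vapply(seq_len(nrow(dirs)), function(i) {
      d <- dirs[i, ]
      hi <- 3; lo <- 0
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (sdf_eval(spec, rbind(mid * d)) < 0) lo <- mid else hi <- mid
      }
      runif(1, 0.8, 0.95) * lo * d
    }, numeric(3)))
    gmag <- sqrt(rowSums(sdf_gradient(spec, pts, h = 1e-7)^2))
    expect_true(all(abs(gmag - 1) < 0.05))
  }
  expect_error(sdf_shape("pyramid", radius = 1), "'arg' should be one of")
})
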