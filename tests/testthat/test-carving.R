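# CSG-subtraction drilling, isosurface extraction, volume accounting.

make_plate_grid <- function(spacing = 0.02e-3, half = c(1e-3, 1e-3),
                            thickness = 0.25e-3, pad = 0.25e-3) {
  dims <- c(round(2 * half / spacing) + 1, round((thickness + 2 * pad) / spacing) + 1)
  g <- sdf_grid(c(-half[1], -half[2], -pad), spacing, dims)
  primitive_sdf(sdf_shape("box", half_extents = c(2 * half[1], 2 * half[2],
                                                  thickness / 2)),
                g, rigid_pose(c(0, 0, thickness / 2)))
}

test_that("the carve update is max(surface, -tool), voxelwise", {
  g <- sdf_grid(c(0, 0, 0), 1e-4, c(5, 5, 5))
  g$values[] <- -0.2e-3                      # uniform material
  burr <- sdf_shape("sphere", radius = 1.5e-4)
  # tool centred on voxel (3,3,3): tool SDF there = -1.5e-4
  cv <- carve(g, burr, rigid_pose(c(2e-4, 2e-4, 2e-4)))
  expect_equal(cv$surface$values[3, 3, 3], 1.5e-4)        # max(-2e-4, +1.5e-4)
  # far voxel untouched: max(-2e-4, -(large)) = -2e-4
  expect_equal(cv$surface$values[1, 1, 1],
               max(-2e-4, -as.numeric(sdf_eval(burr, rbind(c(0, 0, 0)),
                                               rigid_pose(c(2e-4, 2e-4, 2e-4))))))
  expect_gte(cv$result$removed, 0)
  expect_equal(cv$result$cumulative, cv$surface$carved_total)
  # inactive drill changes nothing
  cv2 <- carve(cv$surface, burr, rigid_pose(c(2e-4, 2e-4, 2e-4)), active = FALSE)
  expect_identical(cv2$surface$values, cv$surface$values)
  expect_equal(cv2$result$removed, 0)
  expect_error(carve(g, burr, rigid_pose(c(NaN, 0, 0))), "finite|non-finite")
})

test_that("carving is monotone, idempotent, local, and disjoint carves commute", {
  set.seed(11)
  g0 <- make_plate_grid(spacing = 0.05e-3)
  burr <- sdf_shape("sphere", radius = 0.2e-3)
  g <- g0
  for (i in 1:5) {
    pose <- rigid_pose(c(runif(1, -8e-4, 8e-4), runif(1, -8e-4, 8e-4),
                         runif(1, -1e-4, 3e-4)))
    g1 <- carve(g, burr, pose)$surface
    # monotonicity: no voxel value ever decreases
    expect_true(all(g1$values >= g$values - 1e-300))
    # idempotence: the same pose again changes nothing
    g2 <- carve(g1, burr, pose)
    expect_identical(g2$surface$values, g1$values)
    expect_equal(g2$result$removed, 0)
    g <- g1
  }
  # locality: voxels outside the padded tool box are bit-identical
  pose <- rigid_pose(c(0, 0, 0))
  gl <- carve(g0, burr, pose)
  reg <- gl$result$region
  outside <- g0$values
  outside[reg[1, 1]:reg[2, 1], reg[1, 2]:reg[2, 2], reg[1, 3]:reg[2, 3]] <- NA
  after <- gl$surface$values
  after[reg[1, 1]:reg[2, 1], reg[1, 2]:reg[2, 2], reg[1, 3]:reg[2, 3]] <- NA
  expect_identical(outside, after)
  # two disjoint carves commute exactly
  pa <- rigid_pose(c(-0.6e-3, -0.6e-3, 0)); pb <- rigid_pose(c(0.6e-3, 0.6e-3, 0))
  gab <- carve(carve(g0, burr, pa)$surface, burr, pb)$surface
  gba <- carve(carve(g0, burr, pb)$surface, burr, pa)$surface
  expect_identical(gab$values, gba$values)
})

test_that("a straight plunge removes the analytic swept volume", {
  # 0.3 mm-radius burr straight through a 0.25 mm plate at 0.02 mm spacing:
  # swept volume inside the slab is the pi r^2 t cylinder
  g <- make_plate_grid(spacing = 0.02e-3)
  burr <- sdf_shape("sphere", radius = 0.3e-3)
  for (z in seq(-0.4e-3, 0.6e-3, by = 0.01e-3)) {
    g <- carve(g, burr, rigid_pose(c(0, 0, z)))$surface
  }
  analytic <- pi * 0.3^2 * 0.25
  expect_lt(abs(g$carved_total / analytic - 1), 0.05)
})

test_that("extract_surface produces a watertight zero level set", {
  # all-positive grid: empty mesh
  g <- sdf_grid(c(0, 0, 0), 1e-4, c(6, 6, 6))
  empty <- extract_surface(g)
  expect_equal(nrow(empty$triangles), 0L)
  # sphere: vertices on the surface, enclosed volume within 3% at r/20
  r <- 0.5e-3
  gs <- sdf_grid(rep(-0.7e-3, 3), r / 20, c(57, 57, 57))
  gs <- primitive_sdf(sdf_shape("sphere", radius = r), gs)
  surf <- extract_surface(gs)
  d <- sqrt(rowSums(surf$nodes^2))
  expect_true(all(abs(d - r) < r / 20))              # within one voxel
  expect_lt(abs(mesh_volume(surf) / (4 / 3 * pi * r^3) - 1), 0.03)
})

test_that("carved_volume matches analytic removals", {
  r <- 0.4e-3
  g0 <- sdf_grid(rep(-0.6e-3, 3), r / 20, c(61, 61, 61))
  g0 <- primitive_sdf(sdf_shape("sphere", radius = r), g0)
  expect_equal(carved_volume(g0, g0), 0)
  # complete removal of the sphere (one enclosing cutter pass)
  g1 <- carve(g0, sdf_shape("sphere", radius = 5e-3), rigid_pose())$surface
  expect_lt(abs(carved_volume(g0, g1) / (4 / 3 * pi * r^3 * 1e9) - 1), 0.03)
  # binary counting mode agrees more coarsely
  expect_lt(abs(carved_volume(g0, g1, method = "binary") /
                (4 / 3 * pi * r^3 * 1e9) - 1), 0.1)
  # cylinder of radius 0.3 drilled through a plate of thickness t
  t_pl <- 0.25e-3
  gp0 <- make_plate_grid(spacing = 0.02e-3)
  gp1 <- gp0
  burr <- sdf_shape("cylinder", radius = 0.3e-3, half_height = 1e-3)
  gp1 <- carve(gp1, burr, rigid_pose(c(0, 0, t_pl / 2)))$surface
  expect_lt(abs(carved_volume(gp0, gp1) / (pi * 0.3^2 * 0.25) - 1), 0.05)
  expect_error(carved_volume(gp0, g0), "do not match")
})

test_that("drilled-out elements are deactivated by the centroid rule", {
  scene <- default_scene()
  g <- scene$sdfs$footplate
  burr <- sdf_shape("sphere", radius = 0.3e-3)
  for (z in seq(-0.35e-3, 0.6e-3, by = 0.01e-3)) {
    g <- carve(g, burr, rigid_pose(c(0, 0, z)))$surface
  }
  sc2 <- deactivate_drilled_elements(scene, "footplate", g)
  act <- sc2$bodies$footplate$active
  expect_true(any(!act))                       # hole removes elements
  expect_true(any(act))                        # rim remains
  # the deactivated centroids all lie in the carved void
  cent <- otosim:::elem_centroids(scene$bodies$footplate$mesh$nodes,
                                  scene$bodies$footplate$mesh$tetrahedra)
  val <- otosim:::sdf_grid_interp(g, cent)
  expect_true(all(val[!act] > 0))
})
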