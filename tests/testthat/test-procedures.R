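# Scripted procedures and their recorded metrics.

test_that("trajectories validate, interpolate and apply the homothetic scale", {
  df <- data.frame(t = c(0, 1, 2), x = c(0, 7e-3, 14e-3), y = 0, z = 0,
                   qw = 1, qx = 0, qy = 0, qz = 0)
  tr <- tool_trajectory(df)
  p <- otosim:::trajectory_pose(tr, 0.5)
  expect_equal(p$pose$t, c(3.5e-3, 0, 0))
  expect_error(tool_trajectory(df[c(1, 1, 2), ]), "strictly increasing")
  expect_error(tool_trajectory(df[, -1]), "missing columns")
  # master-arm homothetic interpretation: translations divided by 7
  tr7 <- tool_trajectory(df, homothetic_translation = 7)
  expect_equal(otosim:::trajectory_pose(tr7, 2)$pose$t, c(2e-3, 0, 0))
})

test_that("an empty (non-drilling) trajectory removes nothing", {
  scene <- default_scene()
  df <- data.frame(t = c(0, 1), x = 0, y = 0, z = -1.5e-3,
                   qw = 1, qx = 0, qy = 0, qz = 0, drill = 0)
  rep0 <- run_stapedotomy(scene, tool_trajectory(df), fem = FALSE)
  expect_equal(rep0$drilled_volume_mm3, 0)
  expect_equal(rep0$hole_diameter_mm, 0)
  expect_equal(rep0$duration_s, 1)
})

test_that("a scripted plunge drills a burr-diameter hole at the target", {
  rep <- stapedotomy_run()
  spacing_mm <- default_scene()$sdfs$footplate$spacing * 1e3
  # effective hole diameter ~ burr diameter within 2 voxels
  expect_lt(abs(rep$hole_diameter_mm - 0.6), 2 * spacing_mm)
  # minimal burr-centre distance to the target ~ 0 within one voxel
  expect_lt(rep$min_target_distance_mm, spacing_mm)
  expect_gt(rep$drilled_volume_mm3, 0.05)
  expect_true(rep$drilled_fraction_pct > 0 && rep$drilled_fraction_pct < 100)
  # drilling far outside the footplate domain is an error
  scene <- default_scene()
  off <- make_plunge_trajectory(scene$target_point + c(5e-3, 0, 0))
  expect_error(run_stapedotomy(scene, off, fem = FALSE), "grid domain")
})

test_that("damage flags follow the per-axis force limits", {
  tr0 <- data.frame(t = 0:2, fx = 0, fy = 0, fz = 0)
  expect_false(any(damage_check(tr0)))
  tr1 <- data.frame(t = 0:2, fx = c(0, 1.0, 0), fy = 0, fz = 0)
  expect_true(damage_check(tr1)[["x"]])        # 1.0 N > 0.9 N limit
  expect_false(damage_check(tr1)[["z"]])
  tr2 <- data.frame(t = 0:2, fx = 0, fy = 0, fz = c(0, -0.8, 0))
  expect_true(damage_check(tr2)[["z"]])        # 0.8 N > 0.7 N limit
  expect_false(damage_check(tr2)[["x"]])
  expect_error(damage_check(data.frame(t = 0, fx = NaN, fy = 0, fz = 0)),
               "non-finite")
  expect_error(safety_thresholds(-1, 1), "positive")
})

test_that("displacement reduction arithmetic handles the edge cases", {
  expect_equal(displacement_reduction(c(total = 0.24), c(total = 0.10))[["total"]],
               100 * (0.24 - 0.10) / 0.24, tolerance = 1e-12)  # 58.33%
  expect_equal(displacement_reduction(c(x = 1), c(x = 1))[["x"]], 0)
  expect_equal(displacement_reduction(c(x = 1), c(x = 0))[["x"]], 100)
  expect_true(is.na(displacement_reduction(c(x = 0), c(x = 0))[["x"]]))
  r <- displacement_reduction(crimp_runs()$single, crimp_runs()$dual)
  expect_named(r, c("total", "x", "y", "z"))
})

test_that("stapedioplasty requires a prepared scene and records engagement", {
  scene <- default_scene()
  tr <- make_crimp_trajectory(scene$tools$forceps$pose0$t, duration = 1)
  expect_error(run_stapedioplasty(scene, tr), "not prepared")
  runs <- crimp_runs()
  for (r in list(runs$single, runs$dual)) {
    expect_true(r$engaged)
    expect_false(any(r$damage))
    expect_equal(r$duration_s, 6)
    expect_true(all(r$incus_peak_mm >= 0))
    expect_gte(r$incus_peak_mm[["total"]], max(r$incus_peak_mm[c("x", "y", "z")]))
  }
  # a trajectory that never touches the incus: no displacement, no engagement
  cfg <- scene_config()
  cfg$prosthesis$loop_centre <- c(-1.6, 0, -4.4)
  far_scene <- prepare_stapedioplasty_scene(build_scene(cfg))
  away <- make_crimp_trajectory(far_scene$tools$forceps$pose0$t,
                                amplitude = -0.2e-3, duration = 2, jitter = 0)
  rep_far <- run_stapedioplasty(far_scene, away)
  expect_false(rep_far$engaged)
  expect_lt(rep_far$incus_peak_mm[["total"]], 1e-6)
})

test_that("peak incus displacement increases with the push amplitude", {
  scene <- prepared_scene()
  peaks <- vapply(c(0.10e-3, 0.17e-3, 0.25e-3), function(a) {
    tr <- make_crimp_trajectory(scene$tools$forceps$pose0$t, amplitude = a,
                                duration = 3, jitter = 0)
    run_stapedioplasty(scene, tr)$incus_peak_mm[["total"]]
  }, 1)
  expect_true(all(diff(peaks) > 0))
})

test_that("visual obstruction time counts tool presence in the viewing cone", {
  scene <- default_scene()
  on_axis <- data.frame(t = seq(0, 1, 0.1), x = 0, y = 0, z = -3e-3)
  off_axis <- data.frame(t = seq(0, 1, 0.1), x = 5e-3, y = 0, z = -3e-3)
  expect_gt(visual_obstruction_time(on_axis, scene), 0.9)
  expect_equal(visual_obstruction_time(off_axis, scene), 0)
})
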