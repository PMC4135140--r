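# Scripted surgical procedures: stapedotomy (footplate drilling) and
# stapedioplasty (prosthesis placement and crimping), with or without a
# second blocking arm, driven by timestamped tool trajectories instead of a
# haptic device. Reported "execution time" is always simulated time.

#' Tool trajectory
#'
#' Timestamped rigid poses of one tool. Columns: `t` (s), `x,y,z` (position),
#' `qw,qx,qy,qz` (unit quaternion), optional `drill` (0/1 burr activation)
#' and `tool_id`. Positions are metres internally; CSV files use mm (see
#' [read_trajectory_csv()]).
#'
#' @param df data frame with the columns above.
#' @param homothetic_translation,homothetic_rotation optional master-arm
#'   scale factors applied on interpretation of teleoperation recordings
#'   (translations divided by the factor about the first pose; rotations
#'   divided by the rotation factor); the defaults (1, 1) leave scripted
#'   trajectories untouched, and 7 / 1 mirrors the robot's master-slave
#'   mapping.
#' @return object of class `tool_trajectory`.
#' @export
tool_trajectory <- function(df, homothetic_translation = 1,
                            homothetic_rotation = 1) {
  need <- c("t", "x", "y", "z", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df))) stop("tool_trajectory: missing columns")
  if (nrow(df) < 1) stop("tool_trajectory: empty trajectory")
  if (any(diff(df$t) <= 0)) stop("tool_trajectory: timestamps must be strictly increasing")
  qn <- sqrt(df$qw^2 + df$qx^2 + df$qy^2 + df$qz^2)
  if (any(abs(qn - 1) > 1e-6)) {
    df[c("qw", "qx", "qy", "qz")] <- df[c("qw", "qx", "qy", "qz")] / qn
  }
  if (homothetic_translation != 1) {
    p0 <- as.numeric(df[1, c("x", "y", "z")])
    df$x <- p0[1] + (df$x - p0[1]) / homothetic_translation
    df$y <- p0[2] + (df$y - p0[2]) / homothetic_translation
    df$z <- p0[3] + (df$z - p0[3]) / homothetic_translation
  }
  if (is.null(df$drill)) df$drill <- 1
  structure(list(df = df), class = "tool_trajectory")
}

# pose at time t (linear position interpolation, nearest-orientation slerp)
trajectory_pose <- function(traj, t) {
  df <- traj$df
  if (t <= df$t[1]) i <- c(1L, 1L) else if (t >= df$t[nrow(df)])
    i <- c(nrow(df), nrow(df))
  else {
    hi <- findInterval(t, df$t) + 1L
    i <- c(hi - 1L, hi)
  }
  if (i[1] == i[2]) {
    w <- 0
  } else {
    w <- (t - df$t[i[1]]) / (df$t[i[2]] - df$t[i[1]])
  }
  p <- (1 - w) * as.numeric(df[i[1], c("x", "y", "z")]) +
       w * as.numeric(df[i[2], c("x", "y", "z")])
  q1 <- as.numeric(df[i[1], c("qw", "qx", "qy", "qz")])
  q2 <- as.numeric(df[i[2], c("qw", "qx", "qy", "qz")])
  if (sum(q1 * q2) < 0) q2 <- -q2
  q <- (1 - w) * q1 + w * q2
  q <- q / sqrt(sum(q^2))
  drill <- df$drill[i[if (w < 0.5) 1 else 2]]
  list(pose = rigid_pose(p, q = q), drill = drill >= 0.5)
}

trajectory_span <- function(traj) diff(range(traj$df$t))

#' Scripted straight burr plunge
#'
#' Descends the burr along +z through `target`, drilling on the way down,
#' then retracts. Used for the scripted stapedotomy.
#'
#' @param target 3-vector (m), the intended stapedotomy centre.
#' @param standoff start height above the target (m).
#' @param overdrive depth past the far plate surface (m).
#' @param plate_thickness footplate thickness (m).
#' @param burr_radius burr radius (m).
#' @param duration total time (s).
#' @param dt sample spacing (s).
#' @export
make_plunge_trajectory <- function(target, standoff = 1.2e-3,
                                   overdrive = 0.15e-3,
                                   plate_thickness = 0.25e-3,
                                   burr_radius = 0.3e-3,
                                   duration = 4, dt = 0.04) {
  z0 <- target[3] - standoff - burr_radius
  z1 <- target[3] + plate_thickness + burr_radius + overdrive
  tt <- seq(0, duration, by = dt)
  half <- duration * 0.6
  z <- ifelse(tt <= half, z0 + (z1 - z0) * tt / half,
              z1 + (z0 - z1) * (tt - half) / (duration - half))
  df <- data.frame(t = tt, x = target[1], y = target[2], z = z,
                   qw = 1, qx = 0, qy = 0, qz = 0,
                   drill = as.numeric(tt <= half))
  tool_trajectory(df)
}

#' Scripted crimp push
#'
#' Moves the forceps (and the grasped prosthesis) along +x with a smooth
#' ramp-and-hold profile, pushing the loop onto the incus long process.
#' Optional seeded band-limited jitter emulates residual hand tremor.
#'
#' @param start 3-vector (m), forceps start position.
#' @param amplitude push amplitude along +x (m).
#' @param duration total time (s).
#' @param dt sample spacing (s).
#' @param jitter jitter amplitude (m, standard deviation before smoothing).
#' @param seed RNG seed for the jitter.
#' @export
make_crimp_trajectory <- function(start, amplitude = 0.25e-3, duration = 6,
                                  dt = 0.04, jitter = 5e-6, seed = 1) {
  tt <- seq(0, duration, by = dt)
  ramp0 <- 0.1 * duration; ramp1 <- 0.7 * duration
  s <- pmin(pmax((tt - ramp0) / (ramp1 - ramp0), 0), 1)
  s <- s * s * (3 - 2 * s)                       # smoothstep
  x <- start[1] + amplitude * s
  set.seed(seed)
  jit <- replicate(3, as.numeric(stats::filter(stats::rnorm(length(tt), 0, jitter),
                                               rep(1 / 5, 5), sides = 2)))
  jit[is.na(jit)] <- 0
  df <- data.frame(t = tt, x = x + jit[, 1], y = start[2] + jit[, 2],
                   z = start[3] + jit[, 3],
                   qw = 1, qx = 0, qy = 0, qz = 0, drill = 0)
  tool_trajectory(df)
}

#' Blocking-tool hold trajectory
#'
#' The second-arm rod held still at its default placement: against the incus
#' long process on the side opposite the prosthesis approach.
#'
#' @param scene the scene (provides the rod rest pose).
#' @param duration hold time (s).
#' @export
make_blocking_trajectory <- function(scene, duration = 6) {
  p <- scene$tools$rod$pose0
  q <- matrix_to_quat(p$R)
  tool_trajectory(data.frame(t = c(0, duration),
                             x = p$t[1], y = p$t[2], z = p$t[3],
                             qw = q[1], qx = q[2], qy = q[3], qz = q[4],
                             drill = 0))
}

matrix_to_quat <- function(R) {
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  if (w > 1e-8) {
    q <- c(w, (R[3, 2] - R[2, 3]) / (4 * w), (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else {
    d <- diag(R)
    i <- which.max(d)
    q <- c(0.5, 0.5, 0.5, 0.5)  # fallback for 180-degree rotations
    q <- switch(i,
      c((R[3, 2] - R[2, 3]), 1 + R[1, 1] - R[2, 2] - R[3, 3],
        R[1, 2] + R[2, 1], R[1, 3] + R[3, 1]),
      c((R[1, 3] - R[3, 1]), R[1, 2] + R[2, 1],
        1 + R[2, 2] - R[1, 1] - R[3, 3], R[2, 3] + R[3, 2]),
      c((R[2, 1] - R[1, 2]), R[1, 3] + R[3, 1], R[2, 3] + R[3, 2],
        1 + R[3, 3] - R[1, 1] - R[2, 2]))
  }
  q / sqrt(sum(q^2))
}

#' Safety force thresholds
#'
#' Forces on the ossicular chain beyond these limits risk incudomalleolar
#' rupture or incus luxation.
#'
#' @param anterior_posterior_limit X-axis limit (N), default 0.9.
#' @param lateral_medial_limit Z-axis limit (N), default 0.7.
#' @export
safety_thresholds <- function(anterior_posterior_limit = 0.9,
                              lateral_medial_limit = 0.7) {
  if (anterior_posterior_limit <= 0 || lateral_medial_limit <= 0)
    stop("safety_thresholds: limits must be positive")
  list(anterior_posterior_limit = anterior_posterior_limit,
       lateral_medial_limit = lateral_medial_limit)
}

#' Damage flags from a force trace
#'
#' A flag per monitored axis is raised when the force magnitude on the
#' ossicles exceeds the axis limit at any sample.
#'
#' @param force_trace data frame or matrix with columns `fx`, `fy`, `fz` (N).
#' @param thresholds a [safety_thresholds()].
#' @return named logical vector `c(x = , z = )`.
#' @export
damage_check <- function(force_trace, thresholds = safety_thresholds()) {
  ft <- as.data.frame(force_trace)
  if (any(!is.finite(as.matrix(ft[c("fx", "fy", "fz")]))))
    stop("damage_check: non-finite force trace")
  c(x = any(abs(ft$fx) > thresholds$anterior_posterior_limit),
    z = any(abs(ft$fz) > thresholds$lateral_medial_limit))
}

#' Percent reduction in incus displacement between two runs
#'
#' `100 * (single - dual) / single` on the peak displacements, per axis and
#' total. Undefined (NA) when the single-run peak is zero.
#'
#' @param single,dual `procedure_report`s from [run_stapedioplasty()], or
#'   named numeric vectors with entries `total`, `x`, `y`, `z` (peaks, mm).
#' @return named numeric vector (percent; may be negative).
#' @export
displacement_reduction <- function(single, dual) {
  pk <- function(r) if (inherits(r, "procedure_report")) r$incus_peak_mm else r
  s <- pk(single); d <- pk(dual)
  out <- 100 * (s - d) / s
  out[s == 0] <- NA_real_
  out
}

new_report <- function(kind, ...) {
  structure(c(list(procedure = kind, schema_version = "1.0"), list(...)),
            class = "procedure_report")
}

#' @exportS3Method base::print
print.procedure_report <- function(x, ...) {
  cat("<procedure_report:", x$procedure, ">\n")
  cat(sprintf("  simulated duration: %.2f s\n", x$duration_s))
  if (!is.null(x$drilled_volume_mm3))
    cat(sprintf("  drilled volume: %.4f mm^3 (%.1f%% of footplate), hole %.3f mm, min target distance %.4f mm\n",
                x$drilled_volume_mm3, x$drilled_fraction_pct,
                x$hole_diameter_mm, x$min_target_distance_mm))
  if (!is.null(x$incus_peak_mm))
    cat(sprintf("  incus peak displacement: total %.4f mm (x %.4f, y %.4f, z %.4f), engaged: %s\n",
                x$incus_peak_mm["total"], x$incus_peak_mm["x"],
                x$incus_peak_mm["y"], x$incus_peak_mm["z"],
                isTRUE(x$engaged)))
  invisible(x)
}

# nodes of a body that still belong to at least one active element
active_nodes <- function(body) {
  el <- switch(body$kind, tet = body$mesh$tetrahedra,
               hex = body$mesh$hexahedra, tri = body$mesh$triangles)
  sort(unique(as.integer(el[body$active, , drop = FALSE])))
}

#' Run a scripted stapedotomy
#'
#' Steps the coupled drilling + FEM + contact loop along a burr trajectory:
#' the signed-distance field of the footplate is carved wherever the burr is
#' active, drilled-out finite elements are deactivated, and burr/ossicle
#' contacts are resolved as unilateral constraints. Reports drilled volume,
#' drilled fraction of the footplate, minimal burr-centre distance to the
#' target, effective hole diameter and the force trace on the stapes.
#'
#' @param scene an `otosim_scene` from [build_scene()].
#' @param traj burr [tool_trajectory()].
#' @param settings [solver_settings()]; defaults from the scene config.
#' @param fem set `FALSE` to skip the mechanical response (carving only).
#' @return a `procedure_report`.
#' @export
run_stapedotomy <- function(scene, traj,
                            settings = do.call(solver_settings, scene$config$solver),
                            fem = TRUE) {
  g0 <- scene$sdfs$footplate
  target <- scene$target_point
  fp_vol0 <- sdf_volume(g0)
  dt <- settings$time_step
  tt <- seq(min(traj$df$t), max(traj$df$t), by = dt)
  burr <- scene$tools$burr$shape

  dyn_bodies <- c("footplate", "superstructure", "incus", "malleus",
                  "tympanic_membrane")
  dyn_bodies <- intersect(dyn_bodies, names(scene$bodies))
  sys <- NULL
  state <- NULL
  if (fem) {
    sys <- assemble_system(scene, dyn_bodies,
                           corotational = settings$corotational)
    state <- mech_state(sys$x0)
  }
  off <- scene_offsets(scene)
  g <- g0
  mind <- Inf
  removed_prev <- 0
  forces <- matrix(0, length(tt), 3)
  resid <- numeric(length(tt))
  path <- matrix(0, length(tt), 3)
  needs_reassembly <- FALSE
  stapes_nodes <- NULL
  if (fem) {
    an <- active_nodes(scene$bodies$footplate)
    stapes_nodes <- match("footplate", dyn_bodies)
    stapes_nodes <- cumsum(c(0, vapply(scene$bodies[dyn_bodies],
                                       function(b) nrow(b$mesh$nodes), 1L)))[
                                         match("footplate", dyn_bodies)] + an
  }

  for (si in seq_along(tt)) {
    tp <- trajectory_pose(traj, tt[si])
    pos <- tp$pose$t
    path[si, ] <- pos
    mind <- min(mind, sqrt(sum((pos - target)^2)))
    # drilling outside the represented footplate domain (laterally) is an
    # error; approaching from above/below the grid is normal tool motion
    hi <- g$origin + (g$dims - 1) * g$spacing
    if (tp$drill && (pos[1] < g$origin[1] || pos[1] > hi[1] ||
                     pos[2] < g$origin[2] || pos[2] > hi[2]))
      stop("run_stapedotomy: trajectory leaves the SDF grid domain")
    cv <- carve(g, burr, tp$pose, active = tp$drill)
    g <- cv$surface
    if (fem) {
      if (cv$result$removed > 0) {
        act_before <- scene$bodies$footplate$active
        scene <- deactivate_drilled_elements(scene, "footplate", g)
        needs_reassembly <- !identical(act_before, scene$bodies$footplate$active)
      }
      if (needs_reassembly) {
        # same node layout, so the state carries across the reassembly
        sys <- assemble_system(scene, dyn_bodies,
                               corotational = settings$corotational)
        needs_reassembly <- FALSE
        an <- active_nodes(scene$bodies$footplate)
        stapes_nodes <- cumsum(c(0, vapply(scene$bodies[dyn_bodies],
                                           function(b) nrow(b$mesh$nodes), 1L)))[
                                             match("footplate", dyn_bodies)] + an
      }
      prep <- be_prepare(state, sys, NULL, settings)
      xs <- matrix(state$x, ncol = 3, byrow = TRUE)
      # contact only where the footplate is still material (rest frame)
      X0s <- matrix(sys$x0, ncol = 3, byrow = TRUE)
      still <- sdf_grid_interp(g, X0s[stapes_nodes, , drop = FALSE])
      solid <- stapes_nodes[!is.na(still) & still < 0]
      cts <- sdf_point_contacts(xs[solid, , drop = FALSE], burr, margin = 0,
                                pose = tp$pose, nodes = solid, tool = "burr",
                                slop = settings$contact_slop)
      sol <- solve_contacts(sys, state, cts, dt, settings, prep = prep)
      state <- be_finalize(prep, sol$impulses, sol$pos_impulses)
      resid[si] <- sol$residual
      if (length(sol$lambda) > 0) {
        fsum <- c(0, 0, 0)
        for (k in seq_along(cts)) fsum <- fsum - sol$lambda[k] * cts[[k]]$normal
        forces[si, ] <- fsum / dt      # force applied to the footplate
      }
    }
  }

  hole <- hole_effective_diameter(g0, g)
  new_report("stapedotomy",
    duration_s = trajectory_span(traj),
    tool_path = data.frame(t = tt, x = path[, 1], y = path[, 2], z = path[, 3]),
    drilled_volume_mm3 = g$carved_total,
    drilled_fraction_pct = 100 * g$carved_total / fp_vol0,
    hole_diameter_mm = hole,
    min_target_distance_mm = mind * 1e3,
    force_trace = data.frame(t = tt, fx = forces[, 1], fy = forces[, 2],
                             fz = forces[, 3]),
    damage = damage_check(data.frame(fx = forces[, 1], fy = forces[, 2],
                                     fz = forces[, 3])),
    max_contact_residual = max(resid),
    carved_sdf = g,
    seed = scene$config$seed)
}

#' Effective diameter of the drilled through-hole
#'
#' Diameter of the largest disc inscribed in the through-hole region of the
#' plate: grid columns that contained material before and contain none
#' after, measured in the x-y plane by a brute-force distance transform.
#'
#' @param before,after footplate [sdf_grid()]s on the same grid.
#' @return diameter in mm (0 when there is no through hole).
#' @export
hole_effective_diameter <- function(before, after) {
  mat_before <- apply(before$values < 0, c(1, 2), any)
  mat_after <- apply(after$values < 0, c(1, 2), any)
  through <- mat_before & !mat_after
  if (!any(through)) return(0)
  not_through <- which(!through, arr.ind = TRUE)
  th_idx <- which(through, arr.ind = TRUE)
  # restrict the complement to a band around the through region for speed
  lo <- pmin(apply(th_idx, 2, min)) - 2; hi <- apply(th_idx, 2, max) + 2
  band <- not_through[not_through[, 1] >= lo[1] - 30 & not_through[, 1] <= hi[1] + 30 &
                      not_through[, 2] >= lo[2] - 30 & not_through[, 2] <= hi[2] + 30, ,
                      drop = FALSE]
  h <- before$spacing
  best <- 0
  for (i in seq_len(nrow(th_idx))) {
    d2 <- (band[, 1] - th_idx[i, 1])^2 + (band[, 2] - th_idx[i, 2])^2
    best <- max(best, sqrt(min(d2)))
  }
  2 * best * h * 1e3
}

#' Prepare a scene for stapedioplasty
#'
#' Performs the scripted stapedotomy (straight plunge at the target, carving
#' only) and the scripted total drilling of the stapes superstructure, then
#' deactivates the drilled finite elements. The resulting scene satisfies
#' the preconditions of [run_stapedioplasty()].
#'
#' @param scene an `otosim_scene`.
#' @return the prepared scene.
#' @export
prepare_stapedioplasty_scene <- function(scene) {
  burr <- scene$tools$burr$shape
  r_burr <- burr$diameter / 2
  g <- scene$sdfs$footplate
  target <- scene$target_point
  th <- scene$config$footplate$thickness * 1e-3
  zs <- seq(target[3] - r_burr - 0.3e-3,
            target[3] + th + r_burr + 0.1e-3, by = g$spacing / 2)
  for (z in zs) {
    g <- carve(g, burr, rigid_pose(c(target[1], target[2], z)))$surface
  }
  scene$sdfs$footplate <- g
  scene <- deactivate_drilled_elements(scene, "footplate", g)
  ablate_superstructure(scene)
}

#' Run a scripted stapedioplasty (prosthesis crimping)
#'
#' Simulates pushing the grasped piston prosthesis so its loop crimps onto
#' the incus long process, with unilateral contacts between the loop and the
#' process and, when a second-arm trajectory is given, between the incus and
#' the rigid blocking rod held at its scripted pose. Records the incus
#' long-process tip displacement trace (peak per axis and peak total), the
#' contact-force trace on the incus, damage flags against the safety
#' thresholds, and the snap-in engagement state.
#'
#' @param scene a prepared scene (see [prepare_stapedioplasty_scene()]).
#' @param traj forceps [tool_trajectory()].
#' @param second_arm optional blocking-rod [tool_trajectory()]; `NULL` runs
#'   the single-tool procedure.
#' @param settings [solver_settings()].
#' @param thresholds [safety_thresholds()].
#' @return a `procedure_report` (`engaged = FALSE` if the loop never snapped
#'   in; that is a result, not an error).
#' @export
run_stapedioplasty <- function(scene, traj, second_arm = NULL,
                               settings = do.call(solver_settings, scene$config$solver),
                               thresholds = safety_thresholds()) {
  if (!isTRUE(scene$superstructure_removed))
    stop("run_stapedioplasty: scene not prepared; call prepare_stapedioplasty_scene()")
  if (scene$sdfs$footplate$carved_total <= 0)
    stop("run_stapedioplasty: no stapedotomy hole in the footplate SDF")
  dt <- settings$time_step
  tt <- seq(min(traj$df$t), max(traj$df$t), by = dt)
  bodies <- names(scene$bodies)
  sys <- assemble_system(scene, bodies, corotational = settings$corotational)
  state <- mech_state(sys$x0)
  off <- sys$offsets

  tipN <- landmark_nodes(scene, "incus_tip")
  baseN <- landmark_nodes(scene, "incus_process_base")
  procN <- landmark_nodes(scene, "incus_process")
  loopN <- landmark_nodes(scene, "loop_nodes")
  r_proc <- scene$config$incus$process_radius * 1e-3
  wire <- scene$config$prosthesis$wire * 1e-3
  engage_thr <- scene$config$prosthesis$engage_threshold * 1e-3
  rod <- scene$tools$rod$shape

  X0 <- matrix(sys$x0, ncol = 3, byrow = TRUE)
  tip0 <- colMeans(X0[tipN, , drop = FALSE])
  p0 <- trajectory_pose(traj, tt[1])$pose
  an_rest <- sys$anchors$rest

  nst <- length(tt)
  disp <- matrix(0, nst, 3)
  forces <- matrix(0, nst, 3)
  resid <- numeric(nst)
  engaged <- logical(nst)
  clear <- numeric(nst)
  path <- matrix(0, nst, 3)
  prev_anchor <- an_rest

  for (si in seq_len(nst)) {
    tp <- trajectory_pose(traj, tt[si])$pose
    path[si, ] <- tp$t
    rel_R <- tp$R %*% t(p0$R)
    anchors <- sweep(sweep(an_rest, 2L, p0$t) %*% t(rel_R), 2L, tp$t, "+")
    avel <- (anchors - prev_anchor) / dt
    prev_anchor <- anchors
    f_ext <- anchor_forces(sys, anchors, avel)
    prep <- be_prepare(state, sys, f_ext, settings)

    xs <- matrix(state$x, ncol = 3, byrow = TRUE)
    tip_c <- colMeans(xs[tipN, , drop = FALSE])
    base_c <- colMeans(xs[baseN, , drop = FALSE])
    cap <- sdf_shape("capsule", a = tip_c, b = base_c, radius = r_proc)
    cts <- sdf_point_contacts(xs[loopN, , drop = FALSE], cap, margin = wire,
                              nodes = loopN, tool = "prosthesis",
                              slop = settings$contact_slop)
    # distribute the reaction onto the process surface nodes around the
    # contact with a continuous hat-function weight (the loop pushes the
    # process where it wraps it, not at the segment handles); a smooth
    # weight avoids impulse chatter when the supporting node set changes
    Xproc <- xs[procN, , drop = FALSE]
    r_hat <- 2.0 * scene$config$incus$cell * 1e-3
    for (k in seq_along(cts)) {
      d <- sqrt(rowSums(sweep(Xproc, 2L, cts[[k]]$point)^2))
      w <- pmax(0, 1 - d / r_hat)
      if (sum(w) <= 0) {
        near4 <- order(d)[1:4]
        w[near4] <- 1
      }
      keep <- which(w > 0)
      cts[[k]]$carrier_nodes <- procN[keep]
      cts[[k]]$carrier_w <- w[keep] / sum(w)
    }
    n_pros <- length(cts)
    if (!is.null(second_arm)) {
      rp <- trajectory_pose(second_arm, tt[si])$pose
      cts2 <- sdf_point_contacts(xs[procN, , drop = FALSE], rod, margin = 0,
                                 pose = rp, nodes = procN, tool = "rod",
                                 slop = settings$contact_slop)
      cts <- c(cts, cts2)
    }
    sol <- solve_contacts(sys, state, cts, dt, settings, prep = prep)
    state <- be_finalize(prep, sol$impulses, sol$pos_impulses)
    resid[si] <- sol$residual

    fsum <- c(0, 0, 0)
    if (length(sol$lambda) > 0) {
      for (k in seq_along(cts)) {
        dir <- if (k <= n_pros) -cts[[k]]$normal else cts[[k]]$normal
        fsum <- fsum + sol$lambda[k] * dir
      }
    }
    forces[si, ] <- fsum / dt

    xs <- matrix(state$x, ncol = 3, byrow = TRUE)
    disp[si, ] <- colMeans(xs[tipN, , drop = FALSE]) - tip0
    snap <- snap_in_state(xs[loopN, , drop = FALSE],
                          colMeans(xs[tipN, , drop = FALSE]),
                          colMeans(xs[baseN, , drop = FALSE]), engage_thr)
    engaged[si] <- snap$engaged
    clear[si] <- snap$clearance
  }

  dmm <- disp * 1e3
  tot <- sqrt(rowSums(dmm^2))
  peak <- c(total = max(tot), x = max(abs(dmm[, 1])),
            y = max(abs(dmm[, 2])), z = max(abs(dmm[, 3])))
  ft <- data.frame(t = tt, fx = forces[, 1], fy = forces[, 2],
                   fz = forces[, 3])
  new_report("stapedioplasty",
    duration_s = trajectory_span(traj),
    tool_path = data.frame(t = tt, x = path[, 1], y = path[, 2], z = path[, 3]),
    incus_peak_mm = peak,
    incus_trace = data.frame(t = tt, x = dmm[, 1], y = dmm[, 2], z = dmm[, 3],
                             total = tot),
    force_trace = ft,
    damage = damage_check(ft, thresholds),
    engaged = any(engaged),
    loop_clearance_mm = clear * 1e3,
    second_arm = !is.null(second_arm),
    max_contact_residual = max(resid),
    seed = scene$config$seed)
}

#' Visual obstruction time
#'
#' Simulated time during which a tool lies inside the speculum viewing cone:
#' the cone through the speculum aperture converging on the target along the
#' microscope (+z) axis.
#'
#' @param tool_path data frame `t, x, y, z` of tool positions (m).
#' @param scene the scene (speculum diameter and target point).
#' @param speculum_z z-position of the speculum aperture plane (m).
#' @return obstructed time (s).
#' @export
visual_obstruction_time <- function(tool_path, scene, speculum_z = -6e-3) {
  tgt <- scene$target_point
  rs <- scene$speculum_diameter / 2
  dz <- tool_path$z - speculum_z
  span <- tgt[3] - speculum_z
  frac <- pmin(pmax((tgt[3] - tool_path$z) / span, 0), 1)
  rcone <- rs * frac
  raxis <- sqrt((tool_path$x - tgt[1])^2 + (tool_path$y - tgt[2])^2)
  inside <- tool_path$z >= speculum_z & tool_path$z <= tgt[3] & raxis < rcone
  if (nrow(tool_path) < 2) return(0)
  dt <- stats::median(diff(tool_path$t))
  sum(inside) * dt
}
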