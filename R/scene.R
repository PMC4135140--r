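# Synthetic middle-ear scene.
#
# Coordinate convention (right-handed): X = anterior-posterior,
# Y = superior-inferior, Z = lateral-medial with +Z pointing toward the inner
# ear. The stapes footplate occupies z in [0, thickness]; the tympanic
# membrane, ossicles and tools lie lateral of it (z < 0). All scene geometry
# is stored in SI units (metres); the configuration is written in mm.

MM <- 1e-3

#' Material parameters
#'
#' @param young_modulus Young's modulus (Pa).
#' @param poisson_ratio Poisson's ratio, in `[0, 0.5)`.
#' @param density mass density (kg/m^3).
#' @param rayleigh_alpha mass-proportional damping coefficient (1/s).
#' @param rayleigh_beta stiffness-proportional damping coefficient (s).
#' @export
material <- function(young_modulus, poisson_ratio = 0.3, density,
                     rayleigh_alpha = 0, rayleigh_beta = 1e-4) {
  if (young_modulus <= 0) stop("material: young_modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("material: poisson_ratio must be in [0, 0.5)")
  if (density <= 0) stop("material: density must be > 0")
  if (rayleigh_alpha < 0 || rayleigh_beta < 0)
    stop("material: Rayleigh coefficients must be >= 0")
  structure(list(young_modulus = young_modulus, poisson_ratio = poisson_ratio,
                 density = density, rayleigh_alpha = rayleigh_alpha,
                 rayleigh_beta = rayleigh_beta),
            class = "otosim_material")
}

#' Tool shape
#'
#' Analytic rigid tool geometry: spherical burr, blocking rod / suction
#' cannula (capsule), microforceps tip (capsule), or the piston grasper.
#'
#' @param kind `"burr"`, `"rod"`, `"forceps"`, or `"piston_grasper"`.
#' @param diameter tool diameter in metres.
#' @param length working length in metres (capsule kinds).
#' @export
tool_shape <- function(kind, diameter, length = NULL) {
  kind <- match.arg(kind, c("burr", "rod", "forceps", "piston_grasper"))
  if (diameter <= 0 || (!is.null(length) && length <= 0))
    stop("tool_shape: dimensions must be positive")
  r <- diameter / 2
  shape <- switch(kind,
    burr = sdf_shape("sphere", radius = r),
    rod = sdf_shape("capsule", a = c(0, 0, -length / 2),
                    b = c(0, 0, length / 2), radius = r),
    forceps = sdf_shape("capsule", a = c(0, 0, -length / 2),
                        b = c(0, 0, length / 2), radius = r),
    piston_grasper = sdf_shape("capsule", a = c(0, 0, -length / 2),
                               b = c(0, 0, length / 2), radius = r))
  structure(list(kind = kind, diameter = diameter, length = length,
                 shape = shape), class = "tool_shape")
}

#' Default scene configuration
#'
#' All dimensions in millimetres, material constants in SI. The defaults
#' build the synthetic middle-ear scene: an elliptic 2.8 x 1.52 mm stapes
#' footplate with annular-ligament springs, a stapes superstructure arch,
#' an incus with its long process, a malleus, a conical tympanic-membrane
#' shell fixed at its annulus, a 0.4 x 4.5 mm piston prosthesis with a
#' crimping loop, and the tool set (0.6 mm burr, blocking rod, forceps).
#'
#' @return nested configuration list.
#' @export
scene_config <- function() {
  list(
    footplate = list(a = 1.4, b = 0.76, thickness = 0.25,
                     cell = c(0.2, 0.19, 0.125)),
    superstructure = list(cell = 0.3),
    incus = list(cell = 0.3, process_radius = 0.12),
    membrane = list(radius = 4, apex_height = 0.8, thickness = 0.074,
                    rings = 4, segments = 16, centre = c(-0.9, 0, -5.3)),
    # the loop starts seated on the long process with a 0.01 mm
    # interference fit (inner offset surface 0.21 vs process 0.12 + wire
    # half-thickness 0.1): the elastic squeeze is the crimp grip
    prosthesis = list(diameter = 0.4, length = 4.5, loop_radius = 0.31,
                      wire = 0.1, loop_centre = c(0, 0, -4.4),
                      opening_deg = 30, segments = 7,
                      engage_threshold = 0.12),
    tools = list(burr_diameter = 0.6, rod_diameter = 0.6, rod_length = 2.5,
                 forceps_diameter = 0.4, forceps_length = 1.0),
    rod_clearance = 0.01,
    speculum_diameter = 6,
    target = c(0, 0, 0),
    grid = list(spacing = 0.02, lower = c(-1.7, -1.1, -0.35),
                upper = c(1.7, 1.1, 0.61)),
    materials = list(
      bone = list(young_modulus = 14.1e9, poisson_ratio = 0.3,
                  density = 2200, rayleigh_alpha = 0, rayleigh_beta = 1e-4),
      membrane = list(young_modulus = 32e6, poisson_ratio = 0.3,
                      density = 1200, rayleigh_alpha = 0, rayleigh_beta = 1e-4),
      prosthesis = list(young_modulus = 344e6, poisson_ratio = 0.3,
                        density = 4.5e3, rayleigh_alpha = 0,
                        rayleigh_beta = 1e-4)),
    springs = list(ligament_stiffness = 100, joint_stiffness = 5000,
                   weld_stiffness = 20000),
    grasp = list(stiffness = 1500, damping = 0.5),
    solver = list(time_step = 0.04, corotational = TRUE, linear_tol = 1e-10,
                  contact_iterations = 400, contact_tol = 1e-9, erp = 0.2,
                  contact_slop = 2e-5),
    seed = 1
  )
}

# recursive merge of user config into defaults; unknown keys are an error
merge_config <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(default) || !is.list(user)) return(user)
  extra <- setdiff(names(user), names(default))
  if (length(extra) > 0)
    stop("unknown configuration key: ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (k in names(user)) default[[k]] <- merge_config(default[[k]], user[[k]],
                                                      paste0(path, ".", k))
  default
}

validate_config <- function(cfg) {
  pos <- function(x, what) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop("configuration error: ", what, " must be positive")
  }
  pos(unlist(cfg$footplate), "footplate dimensions")
  pos(c(cfg$prosthesis$diameter, cfg$prosthesis$length, cfg$prosthesis$wire,
        cfg$prosthesis$loop_radius), "prosthesis dimensions")
  pos(unlist(cfg$tools), "tool dimensions")
  pos(cfg$grid$spacing, "grid spacing")
  pos(cfg$solver$time_step, "time step")
  pos(cfg$speculum_diameter, "speculum diameter")
  for (m in cfg$materials) do.call(material, m)  # reuses material validation
  invisible(cfg)
}

new_body <- function(mesh, mat, kind) {
  nel <- switch(kind, tet = nrow(mesh$tetrahedra), tri = nrow(mesh$triangles),
                hex = nrow(mesh$hexahedra))
  list(mesh = mesh, material = mat, kind = kind, active = rep(TRUE, nel))
}

#' Build the synthetic middle-ear scene
#'
#' Deterministically constructs the full synthetic anatomy, springs, boundary
#' conditions, tools and signed-distance fields from a configuration (see
#' [scene_config()] for defaults and units).
#'
#' @param config configuration list; missing entries take their defaults,
#'   unknown keys raise an error.
#' @return object of class `otosim_scene`.
#' @export
build_scene <- function(config = scene_config()) {
  cfg <- merge_config(scene_config(), config)
  validate_config(cfg)
  mat <- lapply(cfg$materials, function(m) do.call(material, m))

  bodies <- list()
  springs <- NULL
  fixed <- NULL
  landmarks <- list()

  ## --- stapes footplate: voxelized ellipse, z in [0, thickness] ----------
  fp <- cfg$footplate
  h <- fp$cell * MM
  a <- fp$a * MM; b <- fp$b * MM; th <- fp$thickness * MM
  nx <- round(2 * a / h[1]); ny <- round(2 * b / h[2]); nz <- round(th / h[3])
  cand <- as.matrix(expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1), iz = 0:(nz - 1)))
  cx <- -a + (cand[, 1] + 0.5) * h[1]
  cy <- -b + (cand[, 2] + 0.5) * h[2]
  keep <- (cx / a)^2 + (cy / b)^2 < 1
  fp_mesh <- voxel_tet_mesh(cand[keep, , drop = FALSE], h,
                            origin = c(-a, -b, 0), body_label = "footplate")
  bodies$footplate <- new_body(fp_mesh, mat$bone, "tet")
  # annular ligament: one isotropic spring per rim node to a fixed anchor
  rfrac <- sqrt((fp_mesh$nodes[, 1] / a)^2 + (fp_mesh$nodes[, 2] / b)^2)
  rim <- which(rfrac > 0.8)
  springs <- rbind(springs, data.frame(
    body_a = "footplate", node_a = rim, body_b = NA_character_,
    node_b = NA_integer_,
    ax = fp_mesh$nodes[rim, 1], ay = fp_mesh$nodes[rim, 2],
    az = fp_mesh$nodes[rim, 3],
    stiffness = cfg$springs$ligament_stiffness, kind = "cartesian",
    rest_length = 0))
  landmarks$footplate_rim <- list(body = "footplate", nodes = rim)
  landmarks$stapes_out <- list(
    body = "footplate",
    nodes = which.min(rowSums(sweep(fp_mesh$nodes, 2L, c(0, 0, 0))^2)))

  ## --- stapes superstructure: voxel arch on the lateral side -------------
  hs <- cfg$superstructure$cell * MM
  crus <- rbind(
    cbind(4L, 1L, 0:3), cbind(0L, 1L, 0:3),       # two crura
    cbind(0:4, 1L, 4L))                           # head bridge
  # origin: x centred (5 cells wide), y centred (3 cells, crura in the middle
  # row); built rising in +z then mirrored so the arch extends lateral (z < 0)
  ss_origin <- c(-2.5 * hs, -1.5 * hs, 0)
  ss_mesh <- voxel_tet_mesh(crus, hs, origin = ss_origin,
                            body_label = "superstructure")
  # flip z: crura should rise lateral (z < 0)
  ss_nodes <- ss_mesh$nodes
  ss_nodes[, 3] <- -ss_nodes[, 3]
  tets <- ss_mesh$tetrahedra
  tets[, c(3, 4)] <- tets[, c(4, 3)]  # restore positive orientation after mirror
  ss_mesh <- tet_mesh(ss_nodes, tets, "superstructure")
  bodies$superstructure <- new_body(ss_mesh, mat$bone, "tet")
  # weld crura feet to nearest footplate surface nodes
  feet <- which(abs(ss_mesh$nodes[, 3]) < 1e-12)
  for (f in feet) {
    tgt <- which.min(rowSums(sweep(fp_mesh$nodes, 2L, ss_mesh$nodes[f, ])^2))
    springs <- rbind(springs, data.frame(
      body_a = "superstructure", node_a = f, body_b = "footplate",
      node_b = tgt, ax = 0, ay = 0, az = 0,
      stiffness = cfg$springs$weld_stiffness, kind = "cartesian",
      rest_length = 0))
  }
  head_ids <- which(ss_mesh$nodes[, 3] < -4 * hs + 1e-12)
  landmarks$stapes_head <- list(body = "superstructure", nodes = head_ids)

  ## --- incus: body + long process (voxel L-shape) ------------------------
  hi <- cfg$incus$cell * MM
  proc_cells <- cbind(2L, 0:6, 1L)                 # x centred, descending in y
  body_cells <- as.matrix(expand.grid(ix = 0:4, iy = 7:9, iz = 0:2))
  in_mesh <- voxel_tet_mesh(rbind(proc_cells, body_cells), hi,
                            origin = c(-2.5 * hi, -0.9e-3, -4.85e-3),
                            body_label = "incus")
  bodies$incus <- new_body(in_mesh, mat$bone, "tet")
  near <- function(v, x, tol = 1e-9) abs(v - x) < tol
  tipN <- which(near(in_mesh$nodes[, 2], -0.9e-3) &
                in_mesh$nodes[, 3] > -4.6e-3 & in_mesh$nodes[, 3] < -4.2e-3)
  baseN <- which(near(in_mesh$nodes[, 2], 1.2e-3) &
                 near(abs(in_mesh$nodes[, 1]), 0.5 * hi) &
                 in_mesh$nodes[, 3] > -4.6e-3 & in_mesh$nodes[, 3] < -4.2e-3)
  procN <- which(in_mesh$nodes[, 2] < 1.2e-3 + 1e-9 &
                 abs(in_mesh$nodes[, 1]) < 0.5 * hi + 1e-9)
  landmarks$incus_tip <- list(body = "incus", nodes = tipN)
  landmarks$incus_process_base <- list(body = "incus", nodes = baseN)
  landmarks$incus_process <- list(body = "incus", nodes = procN)

  ## --- malleus ------------------------------------------------------------
  hm <- cfg$incus$cell * MM
  ma_mesh <- voxel_tet_mesh(cbind(0L, 0:10, 0L), hm,
                            origin = c(-1.05e-3, -1.2e-3, -4.8e-3),
                            body_label = "malleus")
  bodies$malleus <- new_body(ma_mesh, mat$bone, "tet")

  ## --- tympanic membrane: shallow cone, annulus fixed ---------------------
  mb <- cfg$membrane
  tm <- disc_tri_shell(mb$radius * MM, mb$radius * MM, rings = mb$rings,
                       segments = mb$segments, apex_height = mb$apex_height * MM,
                       thickness = mb$thickness * MM)
  tm_nodes <- sweep(tm$nodes, 2L, mb$centre * MM, "+")  # rim plane at centre z
  rimN <- attr(tm, "rim_nodes")
  tm <- tri_shell(tm_nodes, tm$triangles, mb$thickness * MM)
  bodies$tympanic_membrane <- new_body(tm, mat$membrane, "tri")
  fixed <- rbind(fixed, data.frame(body = "tympanic_membrane", node = rimN))
  landmarks$umbo <- list(body = "tympanic_membrane", nodes = 1L)

  # umbo + first ring to malleus manubrium (stiff isotropic springs)
  tm_attach <- c(1L, 2L, 2L + mb$segments %/% 2)
  for (n in tm_attach) {
    tgt <- which.min(rowSums(sweep(ma_mesh$nodes, 2L, tm_nodes[n, ])^2))
    springs <- rbind(springs, data.frame(
      body_a = "tympanic_membrane", node_a = n, body_b = "malleus",
      node_b = tgt, ax = 0, ay = 0, az = 0,
      stiffness = cfg$springs$joint_stiffness, kind = "cartesian",
      rest_length = 0))
  }

  # incudomalleolar joint: malleus upper nodes to nearest incus-body nodes
  mal_up <- which(ma_mesh$nodes[, 2] > 1.1e-3)
  for (n in mal_up) {
    tgt <- which.min(rowSums(sweep(in_mesh$nodes, 2L, ma_mesh$nodes[n, ])^2))
    springs <- rbind(springs, data.frame(
      body_a = "malleus", node_a = n, body_b = "incus", node_b = tgt,
      ax = 0, ay = 0, az = 0, stiffness = cfg$springs$joint_stiffness,
      kind = "cartesian", rest_length = 0))
  }

  # incudostapedial joint: incus tip to stapes head
  for (n in tipN) {
    tgt <- head_ids[which.min(rowSums(sweep(
      ss_mesh$nodes[head_ids, , drop = FALSE], 2L, in_mesh$nodes[n, ])^2))]
    springs <- rbind(springs, data.frame(
      body_a = "incus", node_a = n, body_b = "superstructure", node_b = tgt,
      ax = 0, ay = 0, az = 0, stiffness = cfg$springs$joint_stiffness,
      kind = "cartesian", rest_length = 0))
  }

  ## --- piston prosthesis: square-section shaft + crimping loop -----------
  pr <- cfg$prosthesis
  r_sh <- pr$diameter / 2 * MM
  lc <- pr$loop_centre * MM
  loop <- arc_hex_mesh(lc, pr$loop_radius * MM, wire = pr$wire * MM,
                       opening_halfangle = pr$opening_deg * pi / 180,
                       segments = pr$segments)
  z_top <- lc[3] + pr$loop_radius * MM + pr$wire * MM
  shaft <- box_hex_mesh(c(lc[1] - r_sh, lc[2] - r_sh, z_top),
                        c(lc[1] + r_sh, lc[2] + r_sh, z_top + pr$length * MM),
                        n = c(1, 1, 9))
  bodies$prosthesis_shaft <- new_body(shaft, mat$prosthesis, "hex")
  bodies$prosthesis_loop <- new_body(loop, mat$prosthesis, "hex")
  # weld the bottom third of the loop arc to the shaft top: the bell is a
  # stiff connection, only the free arms stay wire-compliant
  lo_weld <- which(loop$nodes[, 3] > lc[3] + 0.45 * pr$loop_radius * MM)
  sh_top <- which(near(shaft$nodes[, 3], z_top))
  for (n in lo_weld) {
    tgt <- sh_top[which.min(rowSums(sweep(
      shaft$nodes[sh_top, , drop = FALSE], 2L, loop$nodes[n, ])^2))]
    springs <- rbind(springs, data.frame(
      body_a = "prosthesis_loop", node_a = n, body_b = "prosthesis_shaft",
      node_b = tgt, ax = 0, ay = 0, az = 0,
      stiffness = cfg$springs$weld_stiffness, kind = "cartesian",
      rest_length = 0))
  }
  landmarks$loop_nodes <- list(body = "prosthesis_loop",
                               nodes = seq_len(nrow(loop$nodes)))
  # the forceps grip is a full 6-dof generalized spring: distributing the
  # nodal springs along the whole shaft supplies its angular stiffness
  graspN <- seq_len(nrow(shaft$nodes))
  landmarks$grasp_nodes <- list(body = "prosthesis_shaft", nodes = graspN)

  ## --- tools ---------------------------------------------------------------
  tl <- cfg$tools
  rod_x <- (cfg$incus$process_radius + tl$rod_diameter / 2 +
            cfg$rod_clearance) * MM
  tools <- list(
    burr = list(shape = tool_shape("burr", tl$burr_diameter * MM),
                pose0 = rigid_pose(c(0, 0, -1.5e-3))),
    # blocking rod laid parallel to the long process (axis along y), on the
    # side opposite the prosthesis approach: its contacts oppose the push
    # and centre the process in z
    rod = list(shape = tool_shape("rod", tl$rod_diameter * MM,
                                  tl$rod_length * MM),
               pose0 = rigid_pose(c(rod_x, 0, -4.4e-3),
                                  q = c(cos(pi / 4), sin(pi / 4), 0, 0))),
    forceps = list(shape = tool_shape("forceps", tl$forceps_diameter * MM,
                                      tl$forceps_length * MM),
                   pose0 = rigid_pose(c(lc[1], lc[2], -4.9e-3))))

  ## --- signed distance fields ---------------------------------------------
  g <- cfg$grid
  sp <- g$spacing * MM
  dims <- as.integer(round((g$upper - g$lower) / g$spacing)) + 1L
  fp_grid <- sdf_grid(g$lower * MM, sp, dims)
  xs <- sdf_axis(fp_grid, 1); ys <- sdf_axis(fp_grid, 2); zs <- sdf_axis(fp_grid, 3)
  xy <- as.matrix(expand.grid(x = xs, y = ys))
  d2 <- ellipsoid_signed_distance(xy, c(a, b))            # ellipse cross-section
  dz <- abs(zs - th / 2) - th / 2
  v <- array(0, dims)
  d2m <- matrix(d2, dims[1], dims[2])
  for (k in seq_len(dims[3])) {
    v[, , k] <- pmin(pmax(d2m, dz[k]), 0) +
      sqrt(pmax(d2m, 0)^2 + pmax(dz[k], 0)^2)
  }
  fp_grid$values <- v
  # superstructure SDF: coarser grid around the arch
  ss_sp <- 0.05 * MM
  ss_lo <- c(-0.9e-3, -0.55e-3, -1.6e-3)
  ss_hi <- c(0.9e-3, 0.55e-3, 0.05e-3)
  ss_dims <- as.integer(round((ss_hi - ss_lo) / ss_sp)) + 1L
  ss_grid <- sdf_grid(ss_lo, ss_sp, ss_dims)
  pts <- as.matrix(expand.grid(x = sdf_axis(ss_grid, 1),
                               y = sdf_axis(ss_grid, 2),
                               z = sdf_axis(ss_grid, 3)))
  dist <- rep(Inf, nrow(pts))
  boxes <- list(
    list(lo = ss_origin, hi = ss_origin + c(hs, 3 * hs, 5 * hs)),
    list(lo = ss_origin + c(4 * hs, 0, 0), hi = ss_origin + c(5 * hs, 3 * hs, 5 * hs)),
    list(lo = ss_origin + c(0, 0, 4 * hs), hi = ss_origin + c(5 * hs, 3 * hs, 5 * hs)))
  for (bx in boxes) {
    ctr <- (bx$lo + bx$hi) / 2; he <- (bx$hi - bx$lo) / 2
    pl <- sweep(pts, 2L, ctr)
    pl[, 3] <- -pl[, 3]  # superstructure extends in -z
    dist <- pmin(dist, sdf_local(sdf_shape("box", half_extents = he), pl))
  }
  ss_grid$values <- array(dist, ss_dims)

  scene <- structure(list(
    bodies = bodies, springs = springs, fixed = fixed, tools = tools,
    landmarks = landmarks, target_point = cfg$target * MM,
    speculum_diameter = cfg$speculum_diameter * MM,
    grasp = list(body = "prosthesis_shaft", nodes = graspN,
                 stiffness = cfg$grasp$stiffness, damping = cfg$grasp$damping),
    sdfs = list(footplate = fp_grid, superstructure = ss_grid),
    superstructure_removed = FALSE,
    config = cfg), class = "otosim_scene")
  scene
}

#' @exportS3Method base::print
print.otosim_scene <- function(x, ...) {
  nn <- vapply(x$bodies, function(b) nrow(b$mesh$nodes), 1L)
  cat("<otosim_scene>\n  bodies:",
      paste(sprintf("%s(%d nodes)", names(nn), nn), collapse = ", "),
      "\n  springs:", nrow(x$springs), " fixed nodes:", nrow(x$fixed), "\n")
  invisible(x)
}

# body -> global node index offset table
scene_offsets <- function(scene) {
  nn <- vapply(scene$bodies, function(b) nrow(b$mesh$nodes), 1L)
  off <- cumsum(c(0L, nn[-length(nn)]))
  names(off) <- names(scene$bodies)
  off
}

# global rest positions (3N vector, xyz interleaved per node)
scene_rest_positions <- function(scene) {
  do.call(rbind, lapply(scene$bodies, function(b) b$mesh$nodes))
}

# global node ids for a landmark
landmark_nodes <- function(scene, name) {
  lm <- scene$landmarks[[name]]
  if (is.null(lm)) stop("unknown landmark: ", name)
  scene_offsets(scene)[[lm$body]] + lm$nodes
}
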