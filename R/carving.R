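# Signed-distance-field drilling.
#
# The carve update is the CSG subtraction `surface <- max(surface, -tool)`
# applied voxelwise, restricted to the tool's bounding box padded by one
# voxel (a conservative version of updating only around detected contacts).
# Material can only ever be removed: no voxel value ever decreases.

#' Carve a tool shape out of an SDF grid
#'
#' Applies `value <- max(value, -tool_sdf)` to every voxel inside the tool's
#' padded bounding box. When `active` is `FALSE` (burr not powered) nothing
#' changes. Removed volume is measured by sub-voxel (clamped linear)
#' occupancy before/after the update.
#'
#' @param surface an [sdf_grid()].
#' @param tool a [tool_shape()] or [sdf_shape()].
#' @param pose [rigid_pose()] of the tool.
#' @param active drilling enabled flag.
#' @return list with `surface` (the updated grid) and `result`, a
#'   `carve_result` holding `region` (voxel index bounds, 2 x 3), `removed`
#'   (mm^3 removed by this update) and `cumulative` (mm^3 since the grid was
#'   created).
#' @export
carve <- function(surface, tool, pose = rigid_pose(), active = TRUE) {
  if (!inherits(surface, "sdf_grid")) stop("carve: surface must be an sdf_grid")
  shape <- if (inherits(tool, "tool_shape")) tool$shape else tool
  if (!inherits(shape, "sdf_shape")) stop("carve: tool must be a tool_shape or sdf_shape")
  if (any(!is.finite(pose$t)) || any(!is.finite(pose$R)))
    stop("carve: non-finite tool pose")
  empty <- list(region = matrix(NA_integer_, 2, 3), removed = 0,
                cumulative = surface$carved_total)
  class(empty) <- "carve_result"
  if (!isTRUE(active)) return(list(surface = surface, result = empty))

  # world-space bounding box of the shape, padded by one voxel
  rad <- shape_bound_radius(shape)
  ctr <- pose$t + as.numeric(pose$R %*% shape_bound_centre(shape))
  lo <- ctr - rad - surface$spacing
  hi <- ctr + rad + surface$spacing
  i0 <- pmax(ceiling((lo - surface$origin) / surface$spacing) + 1L, 1L)
  i1 <- pmin(floor((hi - surface$origin) / surface$spacing) + 1L, surface$dims)
  i0 <- as.integer(i0); i1 <- as.integer(i1)
  if (any(i1 < i0)) return(list(surface = surface, result = empty))

  xs <- surface$origin[1] + (seq(i0[1], i1[1]) - 1) * surface$spacing
  ys <- surface$origin[2] + (seq(i0[2], i1[2]) - 1) * surface$spacing
  zs <- surface$origin[3] + (seq(i0[3], i1[3]) - 1) * surface$spacing
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  tv <- sdf_eval(shape, pts, pose)
  old <- surface$values[seq(i0[1], i1[1]), seq(i0[2], i1[2]), seq(i0[3], i1[3])]
  new <- pmax(as.numeric(old), -tv)
  h <- surface$spacing
  occ <- function(v) pmin(pmax(0.5 - v / h, 0), 1)
  removed <- sum(occ(as.numeric(old)) - occ(new)) * h^3 * 1e9   # m^3 -> mm^3
  surface$values[seq(i0[1], i1[1]), seq(i0[2], i1[2]), seq(i0[3], i1[3])] <-
    array(new, dim = i1 - i0 + 1L)
  surface$carved_total <- surface$carved_total + removed
  res <- list(region = rbind(i0, i1), removed = removed,
              cumulative = surface$carved_total)
  class(res) <- "carve_result"
  list(surface = surface, result = res)
}

shape_bound_radius <- function(shape) {
  switch(shape$kind,
    sphere = shape$radius,
    ellipsoid = max(shape$semi_axes),
    capsule = sqrt(sum((shape$b - shape$a)^2)) / 2 + shape$radius,
    cylinder = sqrt(shape$radius^2 + shape$half_height^2),
    box = sqrt(sum(shape$half_extents^2)),
    elliptic_plate = sqrt(max(shape$a, shape$b)^2 + shape$half_thickness^2))
}

shape_bound_centre <- function(shape) {
  if (shape$kind == "capsule") (shape$a + shape$b) / 2 else c(0, 0, 0)
}

#' Occupancy volume of an SDF grid
#'
#' Material volume by voxel integration. `method = "interp"` uses a clamped
#' linear occupancy fraction over one voxel width (sub-voxel accuracy);
#' `method = "binary"` counts voxels with negative value (the brute-force
#' reference mode).
#'
#' @param g an [sdf_grid()].
#' @param method `"interp"` or `"binary"`.
#' @return volume in mm^3.
#' @export
sdf_volume <- function(g, method = c("interp", "binary")) {
  method <- match.arg(method)
  h <- g$spacing
  occ <- if (method == "interp") pmin(pmax(0.5 - g$values / h, 0), 1)
         else g$values < 0
  sum(occ) * h^3 * 1e9
}

#' Volume removed between two SDF states
#'
#' Volume of the region that was material before and is not after, by
#' smoothed-occupancy voxel integration (or binary counting).
#'
#' @param before,after [sdf_grid()]s on the identical grid.
#' @inheritParams sdf_volume
#' @return removed volume in mm^3 (non-negative).
#' @export
carved_volume <- function(before, after, method = c("interp", "binary")) {
  method <- match.arg(method)
  if (!identical(before$dims, after$dims) ||
      !isTRUE(all.equal(before$origin, after$origin)) ||
      !isTRUE(all.equal(before$spacing, after$spacing)))
    stop("carved_volume: grids do not match")
  h <- before$spacing
  if (method == "interp") {
    occ <- function(v) pmin(pmax(0.5 - v / h, 0), 1)
    sum(pmax(occ(before$values) - occ(after$values), 0)) * h^3 * 1e9
  } else {
    sum(before$values < 0 & after$values >= 0) * h^3 * 1e9
  }
}

# Freudenthal tetrahedra of a cube, as corner indices 1..8 with corner order
# 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) 5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
.mt_tets <- rbind(
  c(1L, 2L, 4L, 8L),
  c(1L, 4L, 3L, 8L),
  c(1L, 3L, 7L, 8L),
  c(1L, 7L, 5L, 8L),
  c(1L, 5L, 6L, 8L),
  c(1L, 6L, 2L, 8L))

#' Extract the zero level set of an SDF grid
#'
#' Isosurface extraction by marching tetrahedra (Freudenthal six-tetrahedra
#' decomposition of each voxel cell, linear interpolation along edges),
#' yielding a watertight, consistently outward-oriented triangle mesh of the
#' material boundary. An all-positive grid yields an empty mesh.
#'
#' @param sdf an [sdf_grid()].
#' @return a `tri_shell` (no thickness).
#' @export
extract_surface <- function(sdf) {
  v <- sdf$values
  n <- sdf$dims
  if (all(v >= 0)) return(tri_shell(matrix(numeric(), 0, 3), matrix(integer(), 0, 3)))
  # crossing cells (corners exactly on the level set count as outside)
  inside <- v < 0
  cs <- inside[-n[1], -n[2], -n[3]] + inside[-1, -n[2], -n[3]] +
        inside[-n[1], -1, -n[3]] + inside[-1, -1, -n[3]] +
        inside[-n[1], -n[2], -1] + inside[-1, -n[2], -1] +
        inside[-n[1], -1, -1] + inside[-1, -1, -1]
  cross_idx <- which(cs > 0 & cs < 8)
  if (length(cross_idx) == 0)
    return(tri_shell(matrix(numeric(), 0, 3), matrix(integer(), 0, 3)))
  nc <- n - 1L
  ci <- arrayInd(cross_idx, nc)
  lin <- function(i, j, k) i + n[1] * ((j - 1) + n[2] * (k - 1))
  corner_off <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                      c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
  # edge-keyed vertex pool
  vkey <- new.env(hash = TRUE, size = 4L * length(cross_idx))
  verts <- vector("list", 16L * length(cross_idx))
  nv <- 0L
  tris <- vector("list", 16L * length(cross_idx))
  nt <- 0L
  coords_of <- function(id) {
    k <- (id - 1) %/% (n[1] * n[2])
    r <- (id - 1) %% (n[1] * n[2])
    j <- r %/% n[1]
    i <- r %% n[1]
    sdf$origin + c(i, j, k) * sdf$spacing
  }
  edge_vertex <- function(idA, idB) {
    va <- v[idA]; vb <- v[idB]
    t <- va / (va - vb)
    # snap vertices landing on a grid node to a shared corner key so that
    # coincident vertices merge and the surface stays watertight
    if (t <= 1e-9) key <- paste0("c", idA)
    else if (t >= 1 - 1e-9) key <- paste0("c", idB)
    else key <- if (idA < idB) paste0(idA, "_", idB) else paste0(idB, "_", idA)
    id <- vkey[[key]]
    if (!is.null(id)) return(id)
    p <- coords_of(idA) + t * (coords_of(idB) - coords_of(idA))
    nv <<- nv + 1L
    verts[[nv]] <<- p
    assign(key, nv, envir = vkey)
    nv
  }
  for (cc in seq_len(nrow(ci))) {
    ids <- lin(ci[cc, 1] + corner_off[, 1], ci[cc, 2] + corner_off[, 2],
               ci[cc, 3] + corner_off[, 3])
    vals <- v[ids]
    for (t4 in seq_len(6)) {
      tid <- ids[.mt_tets[t4, ]]
      tvl <- vals[.mt_tets[t4, ]]
      neg <- tvl < 0
      nneg <- sum(neg)
      if (nneg == 0L || nneg == 4L) next
      ineg <- which(neg); ipos <- which(!neg)
      if (nneg == 1L || nneg == 3L) {
        if (nneg == 1L) { apex <- ineg[1]; others <- ipos } else { apex <- ipos[1]; others <- ineg }
        p1 <- edge_vertex(tid[apex], tid[others[1]])
        p2 <- edge_vertex(tid[apex], tid[others[2]])
        p3 <- edge_vertex(tid[apex], tid[others[3]])
        nt <- nt + 1L
        tris[[nt]] <- c(p1, p2, p3, tid[apex], if (nneg == 1L) 1L else -1L)
      } else {
        # two negative: quad between the four crossing edges
        a1 <- ineg[1]; a2 <- ineg[2]; b1 <- ipos[1]; b2 <- ipos[2]
        q11 <- edge_vertex(tid[a1], tid[b1])
        q12 <- edge_vertex(tid[a1], tid[b2])
        q21 <- edge_vertex(tid[a2], tid[b1])
        q22 <- edge_vertex(tid[a2], tid[b2])
        nt <- nt + 1L
        tris[[nt]] <- c(q11, q21, q22, tid[a1], 1L)
        nt <- nt + 1L
        tris[[nt]] <- c(q11, q22, q12, tid[a1], 1L)
      }
    }
  }
  V <- do.call(rbind, verts[seq_len(nv)])
  Tm <- matrix(0L, nt, 3L)
  for (i in seq_len(nt)) {
    tr <- tris[[i]]
    a <- V[tr[1], ]; b <- V[tr[2], ]; c <- V[tr[3], ]
    # orient the normal away from material: away from the negative reference
    # corner (sign +1) or toward it flipped (handled via the stored sign)
    ref <- coords_of(tr[4])
    nrm <- pracma_cross(b - a, c - a)
    out_dir <- ((a + b + c) / 3 - ref) * tr[5]
    if (sum(nrm * out_dir) < 0) tr[2:3] <- tr[c(3, 2)]
    Tm[i, ] <- tr[1:3]
  }
  keep <- Tm[, 1] != Tm[, 2] & Tm[, 2] != Tm[, 3] & Tm[, 1] != Tm[, 3]
  keep <- keep & tri_areas(V, Tm) > 0
  tri_shell(V, Tm[keep, , drop = FALSE])
}

#' Deactivate finite elements removed by drilling
#'
#' Marks elements of a body inactive when the carved signed-distance field
#' says their centroid is no longer material (value > 0). Deactivated
#' elements are excluded from stiffness and mass at the next assembly: the
#' minimal mechanically consistent coupling between drilling and the FEM.
#'
#' @param scene an `otosim_scene`.
#' @param body body name.
#' @param sdf the carved [sdf_grid()].
#' @return the scene with updated `active` flags for that body.
#' @export
deactivate_drilled_elements <- function(scene, body, sdf) {
  b <- scene$bodies[[body]]
  if (is.null(b)) stop("unknown body: ", body)
  cent <- switch(b$kind,
    tet = elem_centroids(b$mesh$nodes, b$mesh$tetrahedra),
    hex = elem_centroids(b$mesh$nodes, b$mesh$hexahedra),
    tri = elem_centroids(b$mesh$nodes, b$mesh$triangles))
  val <- sdf_grid_interp(sdf, cent)
  gone <- !is.na(val) & val > 0
  scene$bodies[[body]]$active <- b$active & !gone
  scene
}

elem_centroids <- function(nodes, elems) {
  k <- ncol(elems)
  out <- matrix(0, nrow(elems), 3)
  for (a in seq_len(k)) out <- out + nodes[elems[, a], , drop = FALSE]
  out / k
}

#' Ablate the stapes superstructure
#'
#' Performs the scripted "total drilling" of the stapes superstructure:
#' carves its whole signed-distance field away with an enclosing spherical
#' cutter and deactivates its finite elements, leaving the footplate (and
#' its annular ligament) in place for prosthesis insertion.
#'
#' @param scene an `otosim_scene`.
#' @return the modified scene (`superstructure_removed` set).
#' @export
ablate_superstructure <- function(scene) {
  g <- scene$sdfs$superstructure
  span <- (g$dims - 1) * g$spacing
  cutter <- sdf_shape("sphere", radius = sqrt(sum(span^2)))
  ctr <- g$origin + span / 2
  cv <- carve(g, cutter, rigid_pose(ctr), active = TRUE)
  scene$sdfs$superstructure <- cv$surface
  scene <- deactivate_drilled_elements(scene, "superstructure", cv$surface)
  scene$superstructure_removed <- TRUE
  scene
}
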