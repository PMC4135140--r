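# Mesh containers and procedural primitives.
#
# Coordinates are unit-agnostic: the scene builder works in metres (SI) and
# converts to millimetres only at I/O boundaries. Volumes are returned in the
# cube of whatever unit the nodes carry.

#' Tetrahedral mesh
#'
#' A conforming tetrahedral mesh for an ossicle or other solid body. All
#' tetrahedra must have strictly positive signed volume (consistent
#' orientation, no degenerate elements) and no tetrahedron may appear twice.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z.
#' @param tetrahedra integer matrix, one row per element, 4 node indices.
#' @param body_label name of the body (e.g. `"incus"`).
#' @return object of class `tet_mesh` with fields `nodes`, `tetrahedra`,
#'   `body_label`.
#' @export
tet_mesh <- function(nodes, tetrahedra, body_label = "body") {
  nodes <- as_node_matrix(nodes)
  tetrahedra <- as_elem_matrix(tetrahedra, 4L)
  check_indices(tetrahedra, nrow(nodes), "tetrahedra")
  vols <- tet_signed_volumes(nodes, tetrahedra)
  if (any(vols <= 0)) {
    stop("tet_mesh: ", sum(vols <= 0),
         " tetrahedra with non-positive signed volume (degenerate or inverted)")
  }
  key <- apply(tetrahedra, 1L, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) stop("tet_mesh: duplicate tetrahedra")
  structure(list(nodes = nodes, tetrahedra = tetrahedra,
                 body_label = as.character(body_label)),
            class = "tet_mesh")
}

#' Triangular shell mesh
#'
#' A thin shell of constant-strain-triangle membrane elements (the tympanic
#' membrane), or a bare triangle surface (e.g. extracted isosurfaces, for
#' which no thickness is needed).
#'
#' @param nodes numeric matrix n x 3.
#' @param triangles integer matrix, 3 node indices per row.
#' @param thickness membrane thickness (same length unit as nodes), or `NULL`
#'   for a purely geometric surface.
#' @return object of class `tri_shell`.
#' @export
tri_shell <- function(nodes, triangles, thickness = NULL) {
  nodes <- as_node_matrix(nodes)
  triangles <- as_elem_matrix(triangles, 3L)
  check_indices(triangles, nrow(nodes), "triangles")
  if (nrow(triangles) > 0) {
    a <- tri_areas(nodes, triangles)
    if (any(a <= 0)) stop("tri_shell: zero-area triangle")
  }
  if (!is.null(thickness)) {
    if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
      stop("tri_shell: thickness must be a positive scalar")
  }
  structure(list(nodes = nodes, triangles = triangles, thickness = thickness),
            class = "tri_shell")
}

#' Hexahedral mesh
#'
#' Eight-node hexahedra in VTK ordering (four bottom nodes counter-clockwise,
#' then the four top nodes above them). Used for the piston prosthesis.
#'
#' @param nodes numeric matrix n x 3.
#' @param hexahedra integer matrix, 8 node indices per row.
#' @return object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, hexahedra) {
  nodes <- as_node_matrix(nodes)
  hexahedra <- as_elem_matrix(hexahedra, 8L)
  check_indices(hexahedra, nrow(nodes), "hexahedra")
  vols <- hex_volumes(nodes, hexahedra)
  if (any(vols <= 0)) stop("hex_mesh: non-positive hexahedron volume")
  structure(list(nodes = nodes, hexahedra = hexahedra), class = "hex_mesh")
}

as_node_matrix <- function(nodes) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  if (any(!is.finite(nodes))) stop("nodes must be finite")
  dimnames(nodes) <- NULL
  nodes
}

as_elem_matrix <- function(el, k) {
  el <- as.matrix(el)
  if (nrow(el) > 0 && ncol(el) != k) stop("elements must have ", k, " columns")
  if (nrow(el) == 0) el <- matrix(integer(), 0, k)
  storage.mode(el) <- "integer"
  dimnames(el) <- NULL
  el
}

check_indices <- function(el, n, what) {
  if (nrow(el) == 0) return(invisible())
  if (min(el) < 1L || max(el) > n) stop(what, ": node index out of range")
  if (any(apply(el, 1L, anyDuplicated) > 0))
    stop(what, ": repeated node index within an element")
  invisible()
}

# Signed volume of each tetrahedron (positive for right-handed ordering).
tet_signed_volumes <- function(nodes, tets) {
  if (nrow(tets) == 0) return(numeric(0))
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
   a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

tri_areas <- function(nodes, tris) {
  if (nrow(tris) == 0) return(numeric(0))
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Freudenthal decomposition of one hexahedron (VTK corner order) into 6 tets.
# Corner index by (dx,dy,dz): 1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0)
#                             5:(0,0,1) 6:(1,0,1) 7:(1,1,1) 8:(0,1,1)
.hex_tet_table <- rbind(
  c(1L, 2L, 3L, 7L),
  c(1L, 3L, 4L, 7L),
  c(1L, 4L, 8L, 7L),
  c(1L, 8L, 5L, 7L),
  c(1L, 5L, 6L, 7L),
  c(1L, 6L, 2L, 7L))

hex_to_tets <- function(hexes) {
  if (nrow(hexes) == 0) return(matrix(integer(), 0, 4))
  out <- matrix(0L, nrow(hexes) * 6L, 4L)
  for (i in seq_len(6L)) {
    out[seq(i, by = 6L, length.out = nrow(hexes)), ] <-
      hexes[, .hex_tet_table[i, ], drop = FALSE]
  }
  out
}

hex_volumes <- function(nodes, hexes) {
  if (nrow(hexes) == 0) return(numeric(0))
  tv <- tet_signed_volumes(nodes, hex_to_tets(hexes))
  rowSums(matrix(tv, ncol = 6L, byrow = TRUE))
}

#' Mesh volume
#'
#' Volume enclosed by a mesh: sum of signed tetrahedron volumes for a
#' `tet_mesh`, sum of hexahedron volumes (by six-tetrahedron decomposition)
#' for a `hex_mesh`, and the divergence-theorem volume for a closed,
#' consistently oriented `tri_shell`. Additive over disjoint parts; an open
#' triangle surface is rejected.
#'
#' @param mesh a `tet_mesh`, `hex_mesh` or closed `tri_shell`.
#' @return volume in the cube of the node unit (non-negative).
#' @export
mesh_volume <- function(mesh) UseMethod("mesh_volume")

#' @export
mesh_volume.tet_mesh <- function(mesh)
  sum(tet_signed_volumes(mesh$nodes, mesh$tetrahedra))

#' @export
mesh_volume.hex_mesh <- function(mesh)
  sum(hex_volumes(mesh$nodes, mesh$hexahedra))

#' @export
mesh_volume.tri_shell <- function(mesh) {
  tris <- mesh$triangles
  if (nrow(tris) == 0) return(0)
  # closedness: every undirected edge must be shared by exactly two triangles
  # with opposite orientation
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) stop("mesh_volume: triangle surface is not closed")
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key)) stop("mesh_volume: inconsistent triangle orientation")
  p1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tris[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tris[, 3], , drop = FALSE]
  v <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
           p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
           p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  abs(v)
}

# --- procedural primitives -------------------------------------------------

#' Conforming tetrahedral mesh from voxel cells
#'
#' Builds a tetrahedral mesh from a set of axis-aligned grid cells, splitting
#' each cell into six tetrahedra by the Freudenthal decomposition (conforming
#' across shared faces). Used to generate the simplified ossicle bodies.
#'
#' @param cells integer matrix k x 3 of cell indices (0-based).
#' @param h cell size, scalar or length-3.
#' @param origin corner of cell (0,0,0).
#' @param body_label body name.
#' @export
voxel_tet_mesh <- function(cells, h, origin = c(0, 0, 0), body_label = "body") {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (ncol(cells) != 3L || nrow(cells) == 0) stop("cells must be k x 3, k >= 1")
  h <- rep_len(as.numeric(h), 3L)
  if (any(h <= 0)) stop("voxel cell size must be positive")
  # corner nodes of every cell, deduplicated by integer grid key
  off <- rbind(c(0L,0L,0L), c(1L,0L,0L), c(1L,1L,0L), c(0L,1L,0L),
               c(0L,0L,1L), c(1L,0L,1L), c(1L,1L,1L), c(0L,1L,1L))
  corn <- do.call(rbind, lapply(seq_len(8L), function(i)
    sweep(cells, 2L, off[i, ], "+")))
  key <- paste(corn[, 1], corn[, 2], corn[, 3])
  uk <- !duplicated(key)
  unodes <- corn[uk, , drop = FALSE]
  id <- match(key, key[uk])
  nodes <- sweep(sweep(unodes, 2L, h, "*"), 2L, origin, "+")
  hexes <- matrix(id, ncol = 8L)
  tets <- hex_to_tets(hexes)
  neg <- tet_signed_volumes(nodes, tets) < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tet_mesh(nodes, tets, body_label)
}

#' Triangulated disc (optionally conical), elliptic in plan
#'
#' Disc in the x-y plane centred at the origin, semi-axes `a` (x) and `b`
#' (y), with node rings at equal radial fractions. `apex_height` lifts the
#' centre along +z linearly with decreasing radius, producing the shallow
#' cone used for the tympanic membrane.
#'
#' @param a,b semi-axes.
#' @param rings number of radial rings (>= 1).
#' @param segments nodes per ring.
#' @param apex_height height of the centre above the rim plane.
#' @param thickness membrane thickness passed to [tri_shell()].
#' @return a `tri_shell`; attribute `rim_nodes` holds the outer-ring indices.
#' @export
disc_tri_shell <- function(a, b, rings = 4, segments = 16,
                           apex_height = 0, thickness = NULL) {
  if (a <= 0 || b <= 0) stop("disc semi-axes must be positive")
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  nodes <- matrix(c(0, 0, apex_height), 1, 3)
  ring_ids <- vector("list", rings)
  for (j in seq_len(rings)) {
    f <- j / rings
    ring <- cbind(a * f * cos(th), b * f * sin(th), apex_height * (1 - f))
    ring_ids[[j]] <- nrow(nodes) + seq_len(segments)
    nodes <- rbind(nodes, ring)
  }
  tris <- NULL
  r1 <- ring_ids[[1]]
  for (s in seq_len(segments)) {
    s2 <- if (s == segments) 1L else s + 1L
    tris <- rbind(tris, c(1L, r1[s], r1[s2]))
  }
  if (rings > 1) {
    for (j in seq_len(rings - 1)) {
      ri <- ring_ids[[j]]; ro <- ring_ids[[j + 1]]
      for (s in seq_len(segments)) {
        s2 <- if (s == segments) 1L else s + 1L
        tris <- rbind(tris, c(ri[s], ro[s], ro[s2]), c(ri[s], ro[s2], ri[s2]))
      }
    }
  }
  sh <- tri_shell(nodes, tris, thickness)
  attr(sh, "rim_nodes") <- ring_ids[[rings]]
  sh
}

#' Hexahedral box mesh
#'
#' @param lower,upper opposite corners.
#' @param n number of cells per axis (length 3).
#' @export
box_hex_mesh <- function(lower, upper, n = c(1, 1, 1)) {
  n <- rep_len(as.integer(n), 3L)
  if (any(upper <= lower) || any(n < 1L)) stop("invalid box")
  gx <- seq(lower[1], upper[1], length.out = n[1] + 1L)
  gy <- seq(lower[2], upper[2], length.out = n[2] + 1L)
  gz <- seq(lower[3], upper[3], length.out = n[3] + 1L)
  idx <- function(i, j, k) i + (n[1] + 1L) * ((j - 1L) + (n[2] + 1L) * (k - 1L))
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  hexes <- NULL
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    hexes <- rbind(hexes, c(idx(i, j, k), idx(i + 1L, j, k),
                            idx(i + 1L, j + 1L, k), idx(i, j + 1L, k),
                            idx(i, j, k + 1L), idx(i + 1L, j, k + 1L),
                            idx(i + 1L, j + 1L, k + 1L), idx(i, j + 1L, k + 1L)))
  }
  hex_mesh(nodes, hexes)
}

#' Open hexahedral arc (prosthesis loop)
#'
#' A C-shaped wire of hexahedral segments in the x-z plane, extruded along y.
#' The opening is centred on the `+x` direction.
#'
#' @param centre 3-vector, arc centre.
#' @param radius centreline radius.
#' @param wire half-thickness of the square wire section.
#' @param opening_halfangle half-angle (radians) of the gap around +x.
#' @param segments number of hexahedral segments.
#' @export
arc_hex_mesh <- function(centre, radius, wire = 0.05e-3,
                         opening_halfangle = pi / 4, segments = 7) {
  th <- seq(opening_halfangle, 2 * pi - opening_halfangle,
            length.out = segments + 1L)
  nodes <- NULL
  for (t in th) {
    dir <- c(cos(t), 0, sin(t))
    for (r in c(radius - wire, radius + wire)) {
      for (dy in c(-wire, wire)) {
        nodes <- rbind(nodes, centre + r * dir + c(0, dy, 0))
      }
    }
  }
  # per angular station: 4 nodes in order (rin,y-),(rin,y+),(rout,y-),(rout,y+)
  hexes <- NULL
  for (s in seq_len(segments)) {
    a <- (s - 1L) * 4L
    b <- s * 4L
    # bottom quad (station s) then top quad (station s+1), VTK ordering
    hexes <- rbind(hexes, c(a + 1L, a + 3L, a + 4L, a + 2L,
                            b + 1L, b + 3L, b + 4L, b + 2L))
  }
  vols <- hex_volumes(nodes, hexes)
  if (any(vols < 0)) hexes[vols < 0, ] <- hexes[vols < 0, c(4:1, 8:5)]
  hex_mesh(nodes, hexes)
}

#' Subdivided icosahedral sphere mesh
#'
#' Triangulated sphere used as a geometric test fixture (volume converges to
#' the analytic sphere volume with refinement level).
#'
#' @param radius sphere radius.
#' @param level subdivision level (0 = icosahedron).
#' @param centre 3-vector.
#' @export
icosphere <- function(radius = 1, level = 3, centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
             c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
             c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
             c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  for (l in seq_len(level)) {
    mid_env <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_env[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      assign(key, id, envir = mid_env)
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  nodes <- sweep(v * radius, 2L, centre, "+")
  tri_shell(nodes, f)
}
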