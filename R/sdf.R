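# Signed distance fields.
#
# Convention: negative inside material, zero on the surface, positive outside
# (true Euclidean distance for every primitive, including ellipses/ellipsoids
# which are solved by bisection on the standard closest-point equation).

#' Signed-distance grid
#'
#' A regular voxel grid of signed distances sampled at grid nodes
#' `origin + (i-1) * spacing`. Negative values lie inside material.
#'
#' @param origin 3-vector, position of sample (1,1,1).
#' @param spacing scalar voxel spacing (> 0).
#' @param dims integer 3-vector, samples per axis.
#' @param values numeric array `dims`, signed distances; defaults to +Inf
#'   replaced by a large positive constant (empty grid).
#' @export
sdf_grid <- function(origin, spacing, dims, values = NULL) {
  dims <- as.integer(rep_len(dims, 3L))
  if (any(dims < 2L)) stop("sdf_grid: need at least 2 samples per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 1L || spacing <= 0) stop("sdf_grid: spacing must be a positive scalar")
  if (is.null(values)) values <- array(1e3 * spacing * max(dims), dim = dims)
  values <- as.array(values)
  if (!identical(dim(values), dims)) dim(values) <- dims
  if (any(!is.finite(values))) stop("sdf_grid: values must be finite")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = values, carved_total = 0),
            class = "sdf_grid")
}

#' @exportS3Method base::print
print.sdf_grid <- function(x, ...) {
  cat(sprintf("<sdf_grid %d x %d x %d, spacing %.3g, %.1f%% inside>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              100 * mean(x$values < 0)))
  invisible(x)
}

# grid node coordinates along one axis
sdf_axis <- function(g, ax) g$origin[ax] + (seq_len(g$dims[ax]) - 1) * g$spacing

#' Analytic shape specification
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"capsule"`, `"cylinder"`,
#'   `"box"` (a plate is a thin box), `"elliptic_plate"` (extruded ellipse).
#' @param ... kind-specific dimensions: sphere `radius`; ellipsoid
#'   `semi_axes` (length 3); capsule `a`, `b` (segment endpoints), `radius`;
#'   cylinder `radius`, `half_height` (axis = local z); box `half_extents`;
#'   elliptic_plate `a`, `b` (semi-axes in x/y), `half_thickness` (z).
#' @return object of class `sdf_shape`.
#' @export
sdf_shape <- function(kind, ...) {
  kind <- match.arg(kind, c("sphere", "ellipsoid", "capsule", "cylinder",
                            "box", "elliptic_plate"))
  p <- list(...)
  chk <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0)
  ok <- switch(kind,
    sphere = chk(p$radius),
    ellipsoid = chk(p$semi_axes) && length(p$semi_axes) == 3L,
    capsule = chk(p$radius) && length(p$a) == 3L && length(p$b) == 3L,
    cylinder = chk(p$radius) && chk(p$half_height),
    box = chk(p$half_extents) && length(p$half_extents) == 3L,
    elliptic_plate = chk(p$a) && chk(p$b) && chk(p$half_thickness))
  if (!isTRUE(ok)) stop("sdf_shape: invalid or missing dimensions for kind '", kind, "'")
  structure(c(list(kind = kind), p), class = "sdf_shape")
}

#' Rigid pose
#'
#' @param t translation 3-vector.
#' @param R 3x3 rotation matrix, or `q` a unit quaternion `(w,x,y,z)`.
#' @export
rigid_pose <- function(t = c(0, 0, 0), R = diag(3), q = NULL) {
  if (!is.null(q)) R <- quat_to_matrix(q)
  if (any(!is.finite(t)) || any(!is.finite(R))) stop("rigid_pose: non-finite pose")
  list(t = as.numeric(t), R = R)
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Distance from 2D/3D points (rows) to an origin-centred ellipse/ellipsoid
# with semi-axes ax; exact via bisection on the closest-point equation
# sum((ax_i p_i / (t + ax_i^2))^2) = 1, whose left side is decreasing in t.
# Vectorized over points (fixed bisection depth).
ellipsoid_signed_distance <- function(p, ax) {
  p <- abs(as.matrix(p))
  npt <- nrow(p)
  d <- ncol(p)
  implicit <- rowSums(sweep(p, 2L, ax, "/")^2) - 1
  eps <- 1e-12 * max(ax)
  p <- pmax(p, eps)  # keep strictly off the axes
  ax2 <- ax^2
  gfun <- function(t) {
    s <- 0
    for (j in seq_len(d)) s <- s + (ax[j] * p[, j] / (t + ax2[j]))^2
    s - 1
  }
  lo <- rep(-min(ax2) * (1 - 1e-10), npt)
  hi <- pmax(rowSums(sweep(p, 2L, ax, "*")), max(ax2))
  bad <- gfun(hi) > 0
  while (any(bad)) { hi[bad] <- hi[bad] * 2; bad <- gfun(hi) > 0 }
  medial <- gfun(lo) < 0   # numerically at/inside the medial axis
  for (it in 1:110) {
    mid <- (lo + hi) / 2
    up <- gfun(mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  t <- (lo + hi) / 2
  dist2 <- 0
  for (j in seq_len(d)) {
    qj <- ax2[j] * p[, j] / (t + ax2[j])
    dist2 <- dist2 + (qj - p[, j])^2
  }
  out <- sign(implicit) * sqrt(dist2)
  if (any(medial)) out[medial] <- implicit[medial] * min(ax) / 2
  out
}

# evaluate a shape SDF in its local frame; pts is n x 3
sdf_local <- function(shape, pts) {
  pts <- as.matrix(pts)
  switch(shape$kind,
    sphere = sqrt(rowSums(pts^2)) - shape$radius,
    ellipsoid = ellipsoid_signed_distance(pts, shape$semi_axes),
    capsule = {
      a <- shape$a; b <- shape$b
      ab <- b - a
      tt <- pmin(pmax((sweep(pts, 2L, a) %*% ab) / sum(ab^2), 0), 1)
      cl <- sweep(tt %*% t(ab), 2L, a, "+")
      sqrt(rowSums((pts - cl)^2)) - shape$radius
    },
    cylinder = {
      dr <- sqrt(pts[, 1]^2 + pts[, 2]^2) - shape$radius
      dz <- abs(pts[, 3]) - shape$half_height
      pmin(pmax(dr, dz), 0) + sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
    },
    box = {
      q <- sweep(abs(pts), 2L, shape$half_extents)
      inside <- pmin(apply(q, 1L, max), 0)
      inside + sqrt(rowSums(pmax(q, 0)^2))
    },
    elliptic_plate = {
      d2 <- ellipsoid_signed_distance(pts[, 1:2, drop = FALSE],
                                      c(shape$a, shape$b))
      dz <- abs(pts[, 3]) - shape$half_thickness
      pmin(pmax(d2, dz), 0) + sqrt(pmax(d2, 0)^2 + pmax(dz, 0)^2)
    },
    stop("unknown shape kind"))
}

#' Evaluate an analytic SDF at world points
#'
#' @param shape an [sdf_shape()].
#' @param points n x 3 matrix of world positions.
#' @param pose [rigid_pose()] of the shape (local -> world); `NULL` keeps the
#'   shape in its local frame.
#' @return signed distances, negative inside.
#' @export
sdf_eval <- function(shape, points, pose = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) points <- matrix(points, ncol = 3L)
  if (!is.null(pose)) {
    points <- sweep(points, 2L, pose$t) %*% pose$R  # = R^T (p - t), row form
  }
  sdf_local(shape, points)
}

#' Numerical SDF gradient (central differences)
#'
#' @inheritParams sdf_eval
#' @param h finite-difference step.
#' @export
sdf_gradient <- function(shape, points, pose = NULL, h = 1e-6) {
  points <- as.matrix(points)
  g <- matrix(0, nrow(points), 3L)
  for (ax in 1:3) {
    dp <- points; dm <- points
    dp[, ax] <- dp[, ax] + h
    dm[, ax] <- dm[, ax] - h
    g[, ax] <- (sdf_eval(shape, dp, pose) - sdf_eval(shape, dm, pose)) / (2 * h)
  }
  g
}

#' Sample a primitive SDF on a regular grid
#'
#' @param shape an [sdf_shape()] (optionally with a `pose` attached via the
#'   `pose` argument).
#' @param grid either an existing [sdf_grid()] (its geometry is reused) or a
#'   list with `origin`, `spacing`, `dims`.
#' @param pose optional [rigid_pose()].
#' @return an [sdf_grid()] of signed distances.
#' @export
primitive_sdf <- function(shape, grid, pose = NULL) {
  if (!inherits(shape, "sdf_shape")) stop("primitive_sdf: shape must be an sdf_shape")
  if (inherits(grid, "sdf_grid")) {
    g <- sdf_grid(grid$origin, grid$spacing, grid$dims)
  } else {
    g <- sdf_grid(grid$origin, grid$spacing, grid$dims)
  }
  pts <- as.matrix(expand.grid(x = sdf_axis(g, 1), y = sdf_axis(g, 2),
                               z = sdf_axis(g, 3)))
  g$values <- array(sdf_eval(shape, pts, pose), dim = g$dims)
  g
}

# trilinear interpolation of grid values at world points; NA outside domain
sdf_grid_interp <- function(g, points) {
  points <- as.matrix(points)
  u <- sweep(points, 2L, g$origin) / g$spacing  # 0-based continuous index
  n <- g$dims
  out <- rep(NA_real_, nrow(points))
  ok <- u[, 1] >= 0 & u[, 1] <= n[1] - 1 &
        u[, 2] >= 0 & u[, 2] <= n[2] - 1 &
        u[, 3] >= 0 & u[, 3] <= n[3] - 1
  if (!any(ok)) return(out)
  u <- u[ok, , drop = FALSE]
  i0 <- pmin(floor(u), rep(1, nrow(u)) %o% (n - 2))
  f <- u - i0
  v <- g$values
  idx <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  val <-
    idx(0,0,0) * (1-f[,1]) * (1-f[,2]) * (1-f[,3]) +
    idx(1,0,0) *  f[,1]    * (1-f[,2]) * (1-f[,3]) +
    idx(0,1,0) * (1-f[,1]) *  f[,2]    * (1-f[,3]) +
    idx(1,1,0) *  f[,1]    *  f[,2]    * (1-f[,3]) +
    idx(0,0,1) * (1-f[,1]) * (1-f[,2]) *  f[,3]    +
    idx(1,0,1) *  f[,1]    * (1-f[,2]) *  f[,3]    +
    idx(0,1,1) * (1-f[,1]) *  f[,2]    *  f[,3]    +
    idx(1,1,1) *  f[,1]    *  f[,2]    *  f[,3]
  out[ok] <- val
  out
}

# central-difference gradient of grid values at world points (NA outside)
sdf_grid_gradient <- function(g, points) {
  h <- g$spacing / 2
  gr <- matrix(NA_real_, nrow(as.matrix(points)), 3L)
  p <- as.matrix(points)
  for (ax in 1:3) {
    dp <- p; dm <- p
    dp[, ax] <- dp[, ax] + h
    dm[, ax] <- dm[, ax] - h
    gr[, ax] <- (sdf_grid_interp(g, dp) - sdf_grid_interp(g, dm)) / (2 * h)
  }
  gr
}
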