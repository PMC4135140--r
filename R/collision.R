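# Contact detection and unilateral-constraint resolution.
#
# Tools are analytic signed-distance fields (or carved grids); deformable
# meshes are tested point-wise: a node (or a point sampled on an edge or
# triangle) is in contact when its SDF value falls below the margin. The
# unilateral problem (impulse >= 0, post-step gap >= 0, complementarity) is
# solved by projected Gauss-Seidel on the dt-scaled compliance matrix.

#' A unilateral contact record
#'
#' @param point world contact point (m).
#' @param normal outward unit normal (pointing out of the obstacle).
#' @param depth penetration depth (m, >= 0 for emitted contacts).
#' @param node global node index carrying the contact (point side), or `NA`.
#' @param body body name of the point side.
#' @param feature feature id (node/edge/triangle index), free-form.
#' @param tool id of the tool or carrier.
#' @param carrier_nodes,carrier_w optional global node ids and weights of a
#'   deformable carrier (the obstacle side); the reaction `-normal` is
#'   distributed over them.
#' @export
contact <- function(point, normal, depth, node = NA_integer_, body = NA,
                    feature = NA, tool = NA, carrier_nodes = NULL,
                    carrier_w = NULL) {
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("contact: zero normal")
  # depth >= 0 when touching; a small negative depth marks a contact found
  # inside the detection slop (separated, approach-limited)
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nn,
                 depth = depth, node = node, body = body, feature = feature,
                 tool = tool, carrier_nodes = carrier_nodes,
                 carrier_w = carrier_w),
            class = "otosim_contact")
}

#' Point-versus-SDF contact detection
#'
#' One contact is emitted per point whose signed distance is below `margin`:
#' depth is `margin - value` and the normal is the normalized SDF gradient
#' at the point. Points falling outside a grid SDF's domain are treated as
#' not in contact.
#'
#' @param points n x 3 matrix of world positions (m).
#' @param sdf an [sdf_shape()], [tool_shape()] or [sdf_grid()].
#' @param margin detection margin (m, >= 0); use the surface offset of the
#'   probing feature (e.g. a wire radius) to collide offset surfaces.
#' @param pose [rigid_pose()] for analytic shapes.
#' @param nodes optional global node ids matching `points` rows.
#' @param tool tool id stored on the contacts.
#' @return list of [contact()] records.
#' @export
sdf_point_contacts <- function(points, sdf, margin = 0, pose = NULL,
                               nodes = NULL, tool = NA, slop = 0) {
  if (margin < 0) stop("sdf_point_contacts: margin must be >= 0")
  if (slop < 0) stop("sdf_point_contacts: slop must be >= 0")
  points <- as.matrix(points)
  if (inherits(sdf, "tool_shape")) sdf <- sdf$shape
  if (inherits(sdf, "sdf_grid")) {
    val <- sdf_grid_interp(sdf, points)
    hit <- which(!is.na(val) & val < margin + slop)
    if (length(hit) == 0) return(list())
    grad <- sdf_grid_gradient(sdf, points[hit, , drop = FALSE])
  } else {
    val <- sdf_eval(sdf, points, pose)
    hit <- which(val < margin + slop)
    if (length(hit) == 0) return(list())
    grad <- sdf_gradient(sdf, points[hit, , drop = FALSE], pose)
  }
  out <- vector("list", length(hit))
  for (i in seq_along(hit)) {
    gi <- grad[i, ]
    if (any(!is.finite(gi)) || sum(gi^2) == 0) gi <- c(0, 0, 1)
    out[[i]] <- contact(points[hit[i], ], gi, margin - val[hit[i]],
                        node = if (is.null(nodes)) NA_integer_ else nodes[hit[i]],
                        feature = hit[i], tool = tool)
  }
  out
}

#' Contacts of a sampled edge or triangle feature
#'
#' Divides the primitive into a set of points, tests each against the SDF,
#' and keeps the deepest contact of the feature.
#'
#' @param feature list with `kind` (`"edge"` or `"triangle"`) and `vertices`
#'   (2 x 3 or 3 x 3 world coordinates).
#' @param sdf as in [sdf_point_contacts()].
#' @param samples number of samples: per edge (>= 2), or per triangle edge
#'   for the barycentric grid (>= 3 points total).
#' @param margin detection margin (m).
#' @param pose pose for analytic shapes.
#' @return list with at most one deepest [contact()].
#' @export
sample_feature_contacts <- function(feature, sdf, samples = 8, margin = 0,
                                    pose = NULL) {
  V <- as.matrix(feature$vertices)
  if (feature$kind == "edge") {
    if (samples < 2) stop("sample_feature_contacts: need >= 2 samples per edge")
    t <- seq(0, 1, length.out = samples)
    pts <- outer(1 - t, V[1, ]) + outer(t, V[2, ])
  } else if (feature$kind == "triangle") {
    if (samples < 2) stop("sample_feature_contacts: need >= 3 samples per triangle")
    bc <- expand.grid(a = seq(0, 1, length.out = samples),
                      b = seq(0, 1, length.out = samples))
    bc <- bc[bc$a + bc$b <= 1 + 1e-12, ]
    pts <- outer(bc$a, V[1, ]) + outer(bc$b, V[2, ]) +
           outer(1 - bc$a - bc$b, V[3, ])
  } else stop("sample_feature_contacts: unknown feature kind")
  cs <- sdf_point_contacts(pts, sdf, margin, pose)
  if (length(cs) == 0) return(list())
  depths <- vapply(cs, function(c) c$depth, 1)
  best <- cs[[which.max(depths)]]
  best$feature <- feature$kind
  list(best)
}

# build the sparse contact Jacobian (ncontacts x nfree) for a system
contact_jacobian <- function(contacts, sys) {
  m <- length(contacts)
  map <- integer(sys$ndof)
  map[sys$free_idx] <- seq_len(sys$nfree)
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_len(m)) {
    ct <- contacts[[k]]
    if (!is.na(ct$node)) {
      dofs <- 3L * ct$node - 2L + 0:2
      fr <- map[dofs]
      sel <- fr > 0
      if (any(sel)) {
        ii[[length(ii) + 1]] <- rep(k, sum(sel))
        jj[[length(jj) + 1]] <- fr[sel]
        xx[[length(xx) + 1]] <- ct$normal[sel]
      }
    }
    if (!is.null(ct$carrier_nodes)) {
      for (q in seq_along(ct$carrier_nodes)) {
        dofs <- 3L * ct$carrier_nodes[q] - 2L + 0:2
        fr <- map[dofs]
        sel <- fr > 0
        if (any(sel)) {
          ii[[length(ii) + 1]] <- rep(k, sum(sel))
          jj[[length(jj) + 1]] <- fr[sel]
          xx[[length(xx) + 1]] <- -ct$carrier_w[q] * ct$normal[sel]
        }
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(m, sys$nfree))
}

#' Solve the unilateral contact problem
#'
#' Projected Gauss-Seidel on the compliance (Schur-complement) matrix
#' `W = J A^{-1} J'` with `A = M + dt C + dt^2 K`: finds impulses
#' `lambda >= 0` such that the post-step normal velocity satisfies the
#' stabilized non-penetration constraint and `lambda * residual ~ 0`
#' (complementarity) within tolerance.
#'
#' @param sys `system_matrices`.
#' @param state current [mech_state()].
#' @param contacts list of [contact()] records.
#' @param dt time step (s).
#' @param settings [solver_settings()].
#' @param prep optional precomputed step preparation (internal use); when
#'   absent a free-motion step with zero external force is prepared.
#' @return list with `lambda` (N s, per contact), `impulses` (generalized
#'   impulse vector over all dofs), `residual` (max complementarity
#'   residual), `converged`.
#' @export
solve_contacts <- function(sys, state, contacts, dt,
                           settings = solver_settings(time_step = dt),
                           prep = NULL) {
  zero <- list(lambda = numeric(0), impulses = numeric(sys$ndof),
               residual = 0, converged = TRUE)
  if (length(contacts) == 0) return(zero)
  if (is.null(prep)) prep <- be_prepare(state, sys, NULL, settings)
  J <- contact_jacobian(contacts, sys)
  m <- nrow(J)
  # columns of A^{-1} J'
  AinvJt <- as.matrix(Matrix::solve(prep$fac, Matrix::t(J)))
  W <- as.matrix(J %*% AinvJt)
  v_free <- state$v[sys$free_idx] + prep$dv_free
  depths <- vapply(contacts, function(c) c$depth, 1)
  # split-impulse scheme: the velocity pass stops the approach velocity
  # (contacts inside the detection slop may still approach until they
  # touch); the position pass pushes penetrations out without injecting
  # kinetic energy (its correction moves positions only)
  sol_v <- lcp_solve(W, as.numeric(J %*% v_free) - pmin(depths, 0) / dt,
                     settings)
  sol_p <- lcp_solve(W, -settings$erp * pmax(depths, 0) / dt, settings)
  if (!sol_v$converged)
    warning("solve_contacts: contact solve did not fully converge; ",
            "returning best iterate (residual ", signif(sol_v$residual, 3), ")")
  imp <- numeric(sys$ndof)
  imp[sys$free_idx] <- as.numeric(Matrix::t(J) %*% sol_v$lambda)
  pimp <- numeric(sys$ndof)
  pimp[sys$free_idx] <- as.numeric(Matrix::t(J) %*% sol_p$lambda)
  list(lambda = sol_v$lambda, impulses = imp, pos_impulses = pimp,
       lambda_pos = sol_p$lambda,
       residual = max(sol_v$residual, sol_p$residual),
       converged = sol_v$converged && sol_p$converged)
}

# projected Gauss-Seidel with an active-set direct polish: exact
# complementarity even when the compliance matrix is ill-conditioned
# (stiff bone clusters, conforming grip contacts)
lcp_solve <- function(W, b, settings) {
  m <- length(b)
  lambda <- numeric(m)
  diagW <- pmax(diag(W), 1e-300)
  scale_tol <- settings$contact_tol * (1 + max(abs(b)))
  for (it in seq_len(settings$contact_iterations)) {
    delta <- 0
    for (k in seq_len(m)) {
      wk <- sum(W[k, ] * lambda) + b[k]
      new <- max(0, lambda[k] - wk / diagW[k])
      delta <- max(delta, abs(new - lambda[k]) * diagW[k])
      lambda[k] <- new
    }
    if (delta < scale_tol) break
  }
  active <- lambda > 0 | (as.numeric(W %*% lambda) + b) < 0
  ridge <- 1e-12 * mean(diagW)
  for (it in seq_len(4L * m + 8L)) {
    lam <- numeric(m)
    if (any(active)) {
      WA <- W[active, active, drop = FALSE]
      diag(WA) <- diag(WA) + ridge
      lam[active] <- tryCatch(solve(WA, -b[active]),
                              error = function(e) lambda[active])
    }
    if (any(lam < 0)) {
      active[which.min(lam)] <- FALSE
      next
    }
    w <- as.numeric(W %*% lam) + b
    viol <- !active & w < -scale_tol
    if (any(viol)) {
      active[which(!active)[which.min(w[!active])]] <- TRUE
      next
    }
    lambda <- lam
    break
  }
  w <- as.numeric(W %*% lambda) + b
  # normalized complementarity + feasibility residual (dimensionless)
  res_comp <- max(c(0, abs(lambda * w))) / (1 + max(abs(lambda)) * max(abs(w)))
  res_feas <- max(0, -min(w)) / (1 + max(abs(b)))
  residual <- max(res_comp, res_feas)
  list(lambda = lambda, residual = residual,
       converged = residual < settings$contact_tol * 10)
}

#' Grasp attachment
#'
#' The prosthesis is held by the microforceps through a generalized spring:
#' each attached node is pulled toward its pose-transformed anchor.
#'
#' @param nodes global node ids of the attached prosthesis nodes.
#' @param rest n x 3 rest positions of those nodes (m).
#' @param stiffness total spring stiffness (N/m), split evenly over nodes.
#' @param damping total damping (N s/m).
#' @export
grasp_attachment <- function(nodes, rest, stiffness, damping = 0) {
  if (stiffness <= 0) stop("grasp_attachment: stiffness must be > 0")
  structure(list(nodes = nodes, rest = as.matrix(rest),
                 stiffness = stiffness, damping = damping),
            class = "grasp_attachment")
}

#' Generalized-spring grasp force
#'
#' Force on each attached node:
#' `-k (x - anchor) - c (v - anchor_velocity)` with `anchor` the rest
#' position transported by the tool pose. Zero at coincidence, linear in the
#' displacement.
#'
#' @param att a [grasp_attachment()].
#' @param pose current tool [rigid_pose()] relative to the grasp frame at
#'   attachment time (identity keeps anchors at rest).
#' @param state [mech_state()] providing node positions/velocities.
#' @param anchor_vel n x 3 anchor velocities (m/s), default zero.
#' @return n x 3 matrix of nodal forces (N).
#' @export
grasp_spring_force <- function(att, pose, state, anchor_vel = NULL) {
  n <- length(att$nodes)
  anchors <- sweep(att$rest %*% t(pose$R), 2L, pose$t, "+")
  xs <- matrix(state$x, ncol = 3, byrow = TRUE)[att$nodes, , drop = FALSE]
  vs <- matrix(state$v, ncol = 3, byrow = TRUE)[att$nodes, , drop = FALSE]
  if (is.null(anchor_vel)) anchor_vel <- matrix(0, n, 3)
  kper <- att$stiffness / n
  cper <- att$damping / n
  -kper * (xs - anchors) - cper * (vs - anchor_vel)
}

#' Snap-in engagement state of the prosthesis loop
#'
#' The loop is engaged when the incus long process lies inside the loop
#' aperture beyond the detent: the in-plane distance from the loop centre to
#' the process axis is below the engage threshold. Monotone in the push
#' progress along the approach axis.
#'
#' @param loop_points n x 3 current positions of the loop nodes (m).
#' @param axis_a,axis_b endpoints of the process axis (m).
#' @param engage_threshold centreline clearance below which the loop counts
#'   as engaged (m).
#' @return list with `engaged` (logical) and `clearance` (m).
#' @export
snap_in_state <- function(loop_points, axis_a, axis_b, engage_threshold) {
  ctr <- colMeans(as.matrix(loop_points))
  ab <- axis_b - axis_a
  t <- sum((ctr - axis_a) * ab) / sum(ab^2)
  closest <- axis_a + max(0, min(1, t)) * ab
  clearance <- sqrt(sum((ctr - closest)^2))
  list(engaged = clearance < engage_threshold, clearance = clearance)
}
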