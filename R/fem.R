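# Finite-element dynamics: linear tetrahedra, constant-strain-triangle
# membranes, lumped mass, Rayleigh damping, implicit backward Euler with an
# optional corotational correction for the ossicle tetrahedra.

#' Stiffness of a linear tetrahedral element
#'
#' Standard isotropic linear-elastic 4-node tetrahedron: `K = V B' D B` with
#' the constant strain-displacement matrix `B` from the shape-function
#' gradients and the 3-D isotropic constitutive matrix `D` in Voigt order
#' (xx, yy, zz, yz, xz, xy; engineering shear strains).
#'
#' @param coords 4 x 3 node coordinate matrix (m).
#' @param young Young's modulus (Pa).
#' @param poisson Poisson's ratio.
#' @return 12 x 12 symmetric positive-semidefinite matrix with exactly six
#'   rigid-body zero modes. Dof order: (x1,y1,z1, x2,...).
#' @export
tet_element_stiffness <- function(coords, young, poisson) {
  coords <- as.matrix(coords)
  Dm <- t(coords[2:4, , drop = FALSE]) - coords[1, ]
  vol <- det(Dm) / 6
  if (!is.finite(vol) || vol <= 0)
    stop("tet_element_stiffness: degenerate or inverted element")
  # gradients of the 4 linear shape functions (rows)
  G234 <- solve(Dm)            # rows: grad N2, N3, N4 (as d xi / d x rows)
  grads <- rbind(-colSums(G234), G234)
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[a, ]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1]
    B[2, c0 + 2] <- g[2]
    B[3, c0 + 3] <- g[3]
    B[4, c0 + 2] <- g[3]; B[4, c0 + 3] <- g[2]
    B[5, c0 + 1] <- g[3]; B[5, c0 + 3] <- g[1]
    B[6, c0 + 1] <- g[2]; B[6, c0 + 2] <- g[1]
  }
  lam <- young * poisson / ((1 + poisson) * (1 - 2 * poisson))
  mu <- young / (2 * (1 + poisson))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  K <- vol * t(B) %*% D %*% B
  (K + t(K)) / 2
}

#' Stiffness of a constant-strain-triangle membrane element
#'
#' Plane-stress CST membrane: the element resists in-plane strain only,
#' scaled linearly by thickness; it has no bending or transverse stiffness.
#' The 9 x 9 matrix is the in-plane 6 x 6 stiffness lifted to 3-D world
#' coordinates through the element's local orthonormal frame.
#'
#' @param coords 3 x 3 node coordinates (m).
#' @param young Young's modulus (Pa).
#' @param poisson Poisson's ratio.
#' @param thickness membrane thickness (m).
#' @return 9 x 9 symmetric matrix (dofs x1,y1,z1,x2,...).
#' @export
cst_membrane_stiffness <- function(coords, young, poisson, thickness) {
  coords <- as.matrix(coords)
  if (thickness <= 0) stop("cst_membrane_stiffness: thickness must be > 0")
  e1 <- coords[2, ] - coords[1, ]
  n <- pracma_cross(e1, coords[3, ] - coords[1, ])
  A <- sqrt(sum(n^2)) / 2
  if (A <= 0 || !is.finite(A)) stop("cst_membrane_stiffness: zero-area triangle")
  e1 <- e1 / sqrt(sum(e1^2))
  nn <- n / (2 * A)
  e2 <- pracma_cross(nn, e1)
  # local 2-D coordinates
  P <- sweep(coords, 2L, coords[1, ]) %*% cbind(e1, e2)
  x <- P[, 1]; y <- P[, 2]
  bv <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cv <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  B <- matrix(0, 3, 6)
  for (a in 1:3) {
    B[1, 2 * a - 1] <- bv[a]
    B[2, 2 * a] <- cv[a]
    B[3, 2 * a - 1] <- cv[a]; B[3, 2 * a] <- bv[a]
  }
  B <- B / (2 * A)
  D <- young / (1 - poisson^2) *
    matrix(c(1, poisson, 0, poisson, 1, 0, 0, 0, (1 - poisson) / 2), 3, 3)
  K2 <- thickness * A * t(B) %*% D %*% B
  # lift: local (u,v) of node a = (e1, e2) . world displacement of node a
  T <- matrix(0, 6, 9)
  for (a in 1:3) {
    T[2 * a - 1, 3 * (a - 1) + 1:3] <- e1
    T[2 * a, 3 * (a - 1) + 1:3] <- e2
  }
  K <- t(T) %*% K2 %*% T
  (K + t(K)) / 2
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rayleigh damping matrix
#'
#' `C = alpha * M + beta * K`, exactly.
#'
#' @param M,K mass and stiffness matrices (same shape).
#' @param alpha mass-proportional coefficient (1/s).
#' @param beta stiffness-proportional coefficient (s).
#' @export
rayleigh_damping <- function(M, K, alpha, beta) {
  if (!all(dim(M) == dim(K))) stop("rayleigh_damping: shape mismatch")
  alpha * M + beta * K
}

#' Solver settings
#'
#' @param time_step implicit time step (s); the simulator default is 0.04 s.
#' @param corotational use a per-element corotational frame for tetrahedra.
#' @param linear_tol tolerance of iterative linear solves.
#' @param contact_iterations projected Gauss-Seidel iteration cap.
#' @param contact_tol complementarity tolerance (N s).
#' @param erp penetration error-reduction fraction per step, in (0, 1].
#' @param contact_slop contact detection band (m): contacts activate this
#'   far before touching so pushes settle on the surface without creep.
#' @export
solver_settings <- function(time_step = 0.04, corotational = TRUE,
                            linear_tol = 1e-10, contact_iterations = 400,
                            contact_tol = 1e-9, erp = 0.2,
                            contact_slop = 2e-5) {
  if (time_step <= 0) stop("solver_settings: time_step must be > 0")
  if (linear_tol <= 0 || contact_tol <= 0) stop("solver_settings: tolerances must be > 0")
  list(time_step = time_step, corotational = isTRUE(corotational),
       linear_tol = linear_tol, contact_iterations = contact_iterations,
       contact_tol = contact_tol, erp = erp, contact_slop = contact_slop)
}

#' Mechanical state
#'
#' Nodal positions and velocities (3 dofs per node, xyz interleaved) plus the
#' simulated time.
#'
#' @param x positions (3N vector, m).
#' @param v velocities (3N vector, m/s); defaults to rest.
#' @param time simulated time (s).
#' @export
mech_state <- function(x, v = NULL, time = 0) {
  x <- as.numeric(x)
  if (is.null(v)) v <- numeric(length(x))
  if (length(v) != length(x)) stop("mech_state: inconsistent shapes")
  structure(list(x = x, v = v, time = time), class = "mech_state")
}

#' System matrices directly from components
#'
#' Wraps user-supplied global matrices into the container used by
#' [backward_euler_step()]; useful for reduced test systems. `C` defaults to
#' Rayleigh damping built from `M` and `K`.
#'
#' @param M lumped mass (vector of diagonal entries or diagonal matrix).
#' @param K stiffness matrix (dense or sparse).
#' @param C damping matrix; default `alpha*M + beta*K`.
#' @param x0 rest positions (defaults to the origin).
#' @param alpha,beta Rayleigh coefficients used when `C` is missing.
#' @export
system_matrices <- function(M, K, C = NULL, x0 = NULL, alpha = 0, beta = 0) {
  if (is.matrix(M) || inherits(M, "Matrix")) M <- Matrix::diag(M)
  M <- as.numeric(M)
  K <- methods::as(methods::as(Matrix::Matrix(K, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (is.null(C)) C <- rayleigh_damping(Matrix::Diagonal(x = M), K, alpha, beta)
  n <- length(M)
  if (is.null(x0)) x0 <- numeric(n)
  if (any(M <= 0)) stop("system_matrices: mass must be positive")
  structure(list(ndof = n, M = M, K = K, C = C, x0 = as.numeric(x0),
                 free = rep(TRUE, n), coro = list(), anchors = NULL,
                 nfree = n, free_idx = seq_len(n)),
            class = "system_matrices")
}

# --- assembly from a scene -------------------------------------------------

# triplet accumulator
trip_env <- function() {
  e <- new.env()
  e$i <- vector("list", 64); e$j <- e$i; e$x <- e$i; e$k <- 0L
  e
}
trip_add <- function(e, i, j, x) {
  e$k <- e$k + 1L
  e$i[[e$k]] <- i; e$j[[e$k]] <- j; e$x[[e$k]] <- x
}
trip_mat <- function(e, n) {
  if (e$k == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  }
  Matrix::sparseMatrix(i = unlist(e$i[seq_len(e$k)]),
                       j = unlist(e$j[seq_len(e$k)]),
                       x = unlist(e$x[seq_len(e$k)]), dims = c(n, n))
}

# accumulate w into v at (possibly repeated) indices
acc_add <- function(v, ids, w) {
  agg <- rowsum(w, group = ids)
  idx <- as.integer(rownames(agg))
  v[idx] <- v[idx] + agg[, 1]
  v
}

# expand a small dense block into triplets at global dofs
block_triplets <- function(e, dofs, Kb) {
  nz <- which(Kb != 0, arr.ind = TRUE)
  trip_add(e, dofs[nz[, 1]], dofs[nz[, 2]], Kb[nz])
}

spring_block_axial <- function(d, k) {
  d <- d / sqrt(sum(d^2))
  kb <- k * (d %o% d)
  rbind(cbind(kb, -kb), cbind(-kb, kb))
}

#' Assemble global system matrices from a scene
#'
#' Builds lumped mass, stiffness (tetrahedra + CST membranes + springs,
#' hexahedra via six-tetrahedron decomposition) and Rayleigh damping
#' `C = alpha*M + beta*K` for the selected bodies, eliminating fixed dofs.
#' Deactivated (drilled-away) elements contribute neither stiffness nor
#' mass; nodes left with zero mass and zero stiffness are dropped from the
#' free set.
#'
#' @param scene an `otosim_scene`.
#' @param bodies character vector of body names to include (default: all).
#' @param corotational logical; tetrahedral ossicle elements get a
#'   corotational frame (membranes and springs stay linear).
#' @return object of class `system_matrices` with dof maps and, when
#'   requested, the corotational element cache.
#' @export
assemble_system <- function(scene, bodies = NULL,
                            corotational = scene$config$solver$corotational) {
  if (is.null(bodies)) bodies <- names(scene$bodies)
  missing <- setdiff(bodies, names(scene$bodies))
  if (length(missing)) stop("assemble_system: unknown body ", missing[1])
  sel <- scene$bodies[bodies]
  nn <- vapply(sel, function(b) nrow(b$mesh$nodes), 1L)
  off <- cumsum(c(0L, nn[-length(nn)])); names(off) <- bodies
  ntot <- sum(nn)
  ndof <- 3L * ntot
  X0 <- do.call(rbind, lapply(sel, function(b) b$mesh$nodes))
  x0 <- as.numeric(t(X0))
  Mv <- numeric(ndof)
  e <- trip_env()
  coro <- list()

  for (bn in bodies) {
    b <- sel[[bn]]
    m <- b$material
    o <- off[[bn]]
    if (b$kind == "tet" || b$kind == "hex") {
      tets <- if (b$kind == "tet") b$mesh$tetrahedra else hex_to_tets(b$mesh$hexahedra)
      act <- if (b$kind == "tet") b$active else rep(b$active, each = 6L)
      tets <- tets[act, , drop = FALSE]
      if (nrow(tets) == 0) next
      vols <- tet_signed_volumes(b$mesh$nodes, tets)
      # lumped mass: a quarter of each element mass per node
      for (a in 1:4) {
        ids <- 3L * (o + tets[, a]) - 2L
        for (d in 0:2) {
          Mv <- acc_add(Mv, ids + d, m$density * vols / 4)
        }
      }
      for (t in seq_len(nrow(tets))) {
        nd <- tets[t, ]
        Ke <- tet_element_stiffness(b$mesh$nodes[nd, ], m$young_modulus,
                                    m$poisson_ratio)
        dofs <- as.numeric(t(outer(3L * (o + nd) - 2L, 0:2, "+")))
        if (corotational) {
          Dm <- t(b$mesh$nodes[nd[2:4], ]) - b$mesh$nodes[nd[1], ]
          coro[[length(coro) + 1L]] <- list(dofs = dofs, Ke = Ke,
                                            Dm_inv = solve(Dm),
                                            x0 = as.numeric(t(b$mesh$nodes[nd, ])))
        } else {
          block_triplets(e, dofs, Ke)
        }
      }
    } else if (b$kind == "tri") {
      tris <- b$mesh$triangles[b$active, , drop = FALSE]
      if (nrow(tris) == 0) next
      areas <- tri_areas(b$mesh$nodes, tris)
      for (a in 1:3) {
        ids <- 3L * (o + tris[, a]) - 2L
        for (d in 0:2) {
          Mv <- acc_add(Mv, ids + d, m$density * areas * b$mesh$thickness / 3)
        }
      }
      for (t in seq_len(nrow(tris))) {
        nd <- tris[t, ]
        Ke <- cst_membrane_stiffness(b$mesh$nodes[nd, ], m$young_modulus,
                                     m$poisson_ratio, b$mesh$thickness)
        dofs <- as.numeric(t(outer(3L * (o + nd) - 2L, 0:2, "+")))
        block_triplets(e, dofs, Ke)
      }
    }
  }

  # springs among the selected bodies (others silently skipped)
  sp <- scene$springs
  if (!is.null(sp) && nrow(sp) > 0) {
    for (s in seq_len(nrow(sp))) {
      ba <- sp$body_a[s]
      if (!(ba %in% bodies)) next
      ia <- off[[ba]] + sp$node_a[s]
      if (Mv[3 * ia] == 0 && !node_has_mass_exempt(scene, ba)) next
      if (is.na(sp$body_b[s])) {
        # world-anchored spring
        da <- 3L * ia - 2L + 0:2
        if (sp$kind[s] == "cartesian") {
          kb <- diag(3) * sp$stiffness[s]
          block_triplets(e, da, kb)
        } else {
          d <- c(sp$ax[s], sp$ay[s], sp$az[s]) - X0[ia, ]
          kb <- spring_block_axial(d, sp$stiffness[s])[1:3, 1:3]
          block_triplets(e, da, kb)
        }
      } else {
        bb <- sp$body_b[s]
        if (!(bb %in% bodies)) next
        ib <- off[[bb]] + sp$node_b[s]
        if (Mv[3 * ib] == 0) next
        dofs <- c(3L * ia - 2L + 0:2, 3L * ib - 2L + 0:2)
        if (sp$kind[s] == "cartesian") {
          kb <- diag(3) * sp$stiffness[s]
          block_triplets(e, dofs, rbind(cbind(kb, -kb), cbind(-kb, kb)))
        } else {
          d <- X0[ib, ] - X0[ia, ]
          block_triplets(e, dofs, spring_block_axial(d, sp$stiffness[s]))
        }
      }
    }
  }

  # grasp attachment stiffness (implicit; anchor position supplied per step)
  anchors <- NULL
  if (!is.null(scene$grasp) && scene$grasp$body %in% bodies) {
    gn <- off[[scene$grasp$body]] + scene$grasp$nodes
    kper <- scene$grasp$stiffness / length(gn)
    cper <- scene$grasp$damping / length(gn)
    for (i in gn) block_triplets(e, 3L * i - 2L + 0:2, diag(3) * kper)
    anchors <- list(nodes = gn, k = kper, c = cper, rest = X0[gn, , drop = FALSE])
  }

  K <- trip_mat(e, ndof)
  K <- (K + Matrix::t(K)) / 2

  # fixed dofs
  free <- rep(TRUE, ndof)
  fx <- scene$fixed
  if (!is.null(fx) && nrow(fx) > 0) {
    for (s in seq_len(nrow(fx))) {
      if (!(fx$body[s] %in% bodies)) next
      i <- off[[fx$body[s]]] + fx$node[s]
      free[3L * i - 2L + 0:2] <- FALSE
    }
  }
  # zero-mass dofs: drop when also stiffness-free, otherwise the body is
  # unconstrained plumbing without inertia
  zm <- Mv == 0
  if (any(zm & free)) {
    kdiag <- Matrix::diag(K)
    bad <- zm & free & (kdiag != 0)
    if (any(bad))
      stop("assemble_system: node with stiffness but no mass; ",
           "add elements, fix it, or remove its springs")
    free[zm] <- FALSE
  }

  Kc0 <- NULL
  coro_pack <- NULL
  if (length(coro) > 0) {
    e2 <- trip_env()
    for (el in coro) block_triplets(e2, el$dofs, el$Ke)
    Kc0 <- trip_mat(e2, ndof)
    Kc0 <- (Kc0 + Matrix::t(Kc0)) / 2
    coro_pack <- list(
      dofs = do.call(rbind, lapply(coro, function(el) el$dofs)),
      Dminv = do.call(rbind, lapply(coro, function(el) as.numeric(t(el$Dm_inv)))))
  }

  alpha <- max(vapply(sel, function(b) b$material$rayleigh_alpha, 1))
  beta <- max(vapply(sel, function(b) b$material$rayleigh_beta, 1))
  Kfull <- if (is.null(Kc0)) K else K + Kc0
  C <- rayleigh_damping(Matrix::Diagonal(x = Mv), Kfull, alpha, beta)

  structure(list(ndof = ndof, M = Mv, K = K, C = C, x0 = x0, free = free,
                 free_idx = which(free), nfree = sum(free), coro = coro,
                 Kc0 = Kc0, coro_pack = coro_pack,
                 anchors = anchors, offsets = off, bodies = bodies,
                 alpha = alpha, beta = beta),
            class = "system_matrices")
}

node_has_mass_exempt <- function(scene, body) FALSE

# Corotational correction at configuration x.
#
# All corotational elements contribute linearly through the precomputed
# Kc0; elements whose deformation gradient departs measurably from the
# identity get the polar-decomposition rotation correction (force and
# tangent). Near the rest configuration this reduces exactly to the linear
# model.
coro_forces <- function(sys, x) {
  cp <- sys$coro_pack
  n <- nrow(cp$dofs)
  Xe <- matrix(x[t(cp$dofs)], n, 12, byrow = TRUE)
  # Ds columns: p2-p1, p3-p1, p4-p1 (each 3 components)
  Ds <- Xe[, c(4:6, 7:9, 10:12), drop = FALSE] - Xe[, rep(1:3, 3), drop = FALSE]
  dev <- 0
  Fm <- matrix(0, n, 9)
  for (i in 1:3) for (j in 1:3) {
    Fij <- Ds[, i] * cp$Dminv[, j] +
           Ds[, 3 + i] * cp$Dminv[, 3 + j] +
           Ds[, 6 + i] * cp$Dminv[, 6 + j]
    Fm[, 3 * (j - 1) + i] <- Fij
  }
  dev <- abs(Fm - matrix(rep(as.numeric(diag(3)), each = n), n, 9))
  rot <- which(apply(dev, 1, max) > 1e-7)
  f <- numeric(sys$ndof)
  if (length(rot) == 0) {
    return(list(f = f, K = NULL, rotated = 0L))
  }
  e <- trip_env()
  for (r in rot) {
    el <- sys$coro[[r]]
    xe <- x[el$dofs]
    F <- matrix(Fm[r, ], 3, 3)
    sv <- svd(F)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) {
      u <- sv$u; u[, 3] <- -u[, 3]
      R <- u %*% t(sv$v)
    }
    Rb <- kronecker(diag(4), R)
    fe_rot <- -Rb %*% (el$Ke %*% (crossprod(Rb, xe) - el$x0))
    fe_lin <- -el$Ke %*% (xe - el$x0)
    f[el$dofs] <- f[el$dofs] + as.numeric(fe_rot - fe_lin)
    block_triplets(e, el$dofs, Rb %*% el$Ke %*% t(Rb) - el$Ke)
  }
  list(f = f, K = trip_mat(e, sys$ndof), rotated = length(rot))
}

# elastic force and tangent stiffness at x; anchors contribute through K and
# the per-step anchor offset force handled by the caller
elastic_forces <- function(sys, x) {
  if (length(sys$coro) > 0) {
    Klin <- sys$K + sys$Kc0
    f_lin <- -as.numeric(Klin %*% (x - sys$x0))
    cf <- coro_forces(sys, x)
    if (is.null(cf$K)) list(f = f_lin, K = Klin)
    else list(f = f_lin + cf$f, K = Klin + cf$K)
  } else {
    f_lin <- -as.numeric(sys$K %*% (x - sys$x0))
    list(f = f_lin, K = sys$K)
  }
}

# anchor (grasp) external force for anchor positions `apos` (n x 3 world)
anchor_forces <- function(sys, apos, avel = NULL) {
  f <- numeric(sys$ndof)
  if (is.null(sys$anchors)) return(f)
  an <- sys$anchors
  if (is.null(avel)) avel <- matrix(0, nrow(an$rest), 3)
  dofs <- as.numeric(t(outer(3L * an$nodes - 2L, 0:2, "+")))
  # stiffness about the rest anchor already lives in K; moving the anchor
  # adds k * (anchor - rest) (+ damping on the anchor velocity)
  f[dofs] <- as.numeric(t(an$k * (apos - an$rest) + an$c * avel))
  f
}

# prepare one implicit step: factorization and free-motion velocity update
be_prepare <- function(state, sys, f_ext = NULL, settings = solver_settings()) {
  dt <- settings$time_step
  x <- state$x; v <- state$v
  ef <- elastic_forces(sys, x)
  if (is.null(f_ext)) f_ext <- numeric(sys$ndof)
  fr <- sys$free_idx
  Kff <- ef$K[fr, fr, drop = FALSE]
  Cff <- sys$C[fr, fr, drop = FALSE]
  A <- Matrix::Diagonal(x = sys$M[fr]) + dt * Cff + dt * dt * Kff
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  rhs <- dt * (f_ext[fr] + ef$f[fr] -
               as.numeric(Cff %*% v[fr]) - dt * as.numeric(Kff %*% v[fr]))
  dv <- as.numeric(Matrix::solve(fac, rhs))
  list(fac = fac, dv_free = dv, dt = dt, fr = fr, state = state, sys = sys)
}

be_finalize <- function(prep, impulses = NULL, pos_impulses = NULL) {
  st <- prep$state
  v <- st$v
  dv <- prep$dv_free
  if (!is.null(impulses)) {
    dv <- dv + as.numeric(Matrix::solve(prep$fac, impulses[prep$fr]))
  }
  v[prep$fr] <- v[prep$fr] + dv
  x <- st$x + prep$dt * v
  if (!is.null(pos_impulses)) {
    # split-impulse positional correction: resolves penetration without
    # adding kinetic energy
    dx <- prep$dt * as.numeric(Matrix::solve(prep$fac, pos_impulses[prep$fr]))
    x[prep$fr] <- x[prep$fr] + dx
  }
  x[-prep$fr] <- st$x[-prep$fr]
  mech_state(x, v, st$time + prep$dt)
}

#' One implicit backward-Euler step
#'
#' Solves `(M + dt C + dt^2 K) dv = dt (f_ext + f_el - C v - dt K v)` on the
#' free dofs (with `K` and `f_el` the tangent stiffness and elastic force at
#' the current configuration; corotational if the system was assembled so),
#' adds optional contact impulses through the same operator, then advances
#' `v <- v + dv`, `x <- x + dt v`. Unconditionally stable on the linear
#' system; dissipative for any `dt > 0`.
#'
#' @param state a [mech_state()].
#' @param sys a `system_matrices` object.
#' @param f_ext external force vector (full dofs, N); default zero.
#' @param impulses contact impulse vector (full dofs, N s); default none.
#' @param settings [solver_settings()].
#' @return the advanced [mech_state()].
#' @export
backward_euler_step <- function(state, sys, f_ext = NULL, impulses = NULL,
                                settings = solver_settings()) {
  if (sys$nfree == 0) {
    return(mech_state(state$x, state$v, state$time + settings$time_step))
  }
  prep <- tryCatch(
    be_prepare(state, sys, f_ext, settings),
    error = function(err) stop(
      "backward_euler_step: singular system (a free-floating body with no ",
      "damping or contact?) - add constraints, springs or fixed nodes\n  ",
      conditionMessage(err)))
  be_finalize(prep, impulses)
}
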