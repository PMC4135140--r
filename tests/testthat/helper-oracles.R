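# Independent oracles used across the suite.
#
# The element-stiffness oracles recover the Hessian of an independently
# coded strain-energy functional through the exact quadratic-form identity
# K[i,j] = U(e_i + e_j) - U(e_i) - U(e_j), which holds to machine precision
# for any quadratic U.

# strain energy of a linear tetrahedron under nodal displacement u (12-vec)
tet_strain_energy <- function(coords, young, poisson, u) {
  X <- as.matrix(coords)
  U <- matrix(u, 4, 3, byrow = TRUE)
  E <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])  # rows
  vol <- det(t(E)) / 6
  dU <- rbind(U[2, ] - U[1, ], U[3, ] - U[1, ], U[4, ] - U[1, ])
  H <- t(dU) %*% solve(t(E))    # displacement gradient (3 x 3)
  eps <- (H + t(H)) / 2
  lam <- young * poisson / ((1 + poisson) * (1 - 2 * poisson))
  mu <- young / (2 * (1 + poisson))
  vol * (lam / 2 * sum(diag(eps))^2 + mu * sum(eps * eps))
}

# plane-stress membrane strain energy of a CST under nodal displacement u
cst_strain_energy <- function(coords, young, poisson, thickness, u) {
  X <- as.matrix(coords)
  U <- matrix(u, 3, 3, byrow = TRUE)
  e1 <- X[2, ] - X[1, ]
  nrm <- c(e1[2] * (X[3, 3] - X[1, 3]) - e1[3] * (X[3, 2] - X[1, 2]),
           e1[3] * (X[3, 1] - X[1, 1]) - e1[1] * (X[3, 3] - X[1, 3]),
           e1[1] * (X[3, 2] - X[1, 2]) - e1[2] * (X[3, 1] - X[1, 1]))
  A <- sqrt(sum(nrm^2)) / 2
  e1 <- e1 / sqrt(sum(e1^2))
  n <- nrm / (2 * A)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  P2 <- sweep(X, 2, X[1, ]) %*% cbind(e1, e2)   # local 2-D coordinates
  U2 <- U %*% cbind(e1, e2)                      # in-plane displacements
  M <- rbind(P2[2, ] - P2[1, ], P2[3, ] - P2[1, ])
  dU2 <- rbind(U2[2, ] - U2[1, ], U2[3, ] - U2[1, ])
  H <- t(solve(M) %*% dU2)                       # 2x2 in-plane gradient
  eps <- (H + t(H)) / 2
  D <- young / (1 - poisson^2)
  exx <- eps[1, 1]; eyy <- eps[2, 2]; gxy <- 2 * eps[1, 2]
  dens <- D / 2 * (exx^2 + eyy^2 + 2 * poisson * exx * eyy) +
    D * (1 - poisson) / 2 * gxy^2 / 2
  thickness * A * dens
}

# exact Hessian of a quadratic energy functional
energy_hessian <- function(energy, n) {
  K <- matrix(0, n, n)
  Ui <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1; energy(e)
  }, 1)
  for (i in seq_len(n)) for (j in i:n) {
    e <- numeric(n); e[i] <- e[i] + 1; e[j] <- e[j] + 1
    K[i, j] <- K[j, i] <- energy(e) - Ui[i] - Ui[j]
  }
  diag(K) <- 2 * Ui
  K
}

# a one-body scene-like object for assembly tests
mini_scene <- function(bodies, springs = NULL, fixed = NULL, grasp = NULL) {
  structure(list(bodies = bodies, springs = springs, fixed = fixed,
                 tools = list(), landmarks = list(), grasp = grasp,
                 sdfs = list(), config = list(solver = list(corotational = FALSE))),
            class = "otosim_scene")
}

mini_tet_body <- function(origin = c(0, 0, 0), young = 1e6, density = 1000) {
  nodes <- rbind(c(0, 0, 0), c(1e-3, 0, 0), c(0, 1e-3, 0), c(0, 0, 1e-3))
  nodes <- sweep(nodes, 2, origin, "+")
  mesh <- tet_mesh(nodes, matrix(1:4, 1), "mini")
  list(mesh = mesh, material = material(young, 0.3, density),
       kind = "tet", active = TRUE)
}
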