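# Validation experiments and procedure-quality scoring.
#
# The transfer function mirrors a clinical audiometry: harmonic acoustic
# pressure on the tympanic membrane, stapes-footplate response per unit
# pressure, solved in the frequency domain. The quality score combines
# placement error S, a force functional F, visual obstruction time VF and
# the before/after transfer-function ratio.

#' Ossicular-chain transfer function
#'
#' Steady-state harmonic response `(K + i w C - w^2 M) u = p * a_n` for each
#' frequency, with the load the area-weighted pressure on the tympanic
#' membrane along its normals, read out at the stapes footplate centre node.
#' Linear in the pressure amplitude.
#'
#' @param scene an `otosim_scene`.
#' @param freqs frequencies (Hz).
#' @param pressure amplitude (Pa).
#' @param bodies bodies to include; default: chain + membrane, excluding the
#'   prosthesis and grasp plumbing.
#' @return object of class `tf_result`: `freqs`, `magnitude` (m/Pa,
#'   displacement per unit pressure), `phase` (rad).
#' @export
transfer_function <- function(scene, freqs, pressure = 1,
                              bodies = c("footplate", "superstructure",
                                         "incus", "malleus",
                                         "tympanic_membrane")) {
  bodies <- intersect(bodies, names(scene$bodies))
  sys <- assemble_system(scene, bodies, corotational = FALSE)
  f <- membrane_pressure_load(scene, sys, bodies, pressure)
  out_node <- landmark_nodes_sub(scene, "stapes_out", bodies)
  dof <- 3L * out_node - 2L + 0:2
  hr <- harmonic_response(sys, f, freqs, dof)
  structure(list(freqs = freqs, magnitude = hr$magnitude / pressure,
                 phase = hr$phase, pressure = pressure),
            class = "tf_result")
}

#' Steady-state harmonic response of an assembled system
#'
#' Solves `(K + i w C - w^2 M) u = f` at each angular frequency
#' `w = 2 pi freq` and reports the response magnitude (euclidean over the
#' requested dofs) and the phase of the last requested dof.
#'
#' @param sys a `system_matrices`.
#' @param f real load vector (full dofs).
#' @param freqs frequencies (Hz).
#' @param out_dofs dof indices (1-based, full numbering) to read out.
#' @return list with `magnitude` and `phase` per frequency.
#' @export
harmonic_response <- function(sys, f, freqs, out_dofs) {
  fr <- sys$free_idx
  Kfull <- if (!is.null(sys$Kc0)) sys$K + sys$Kc0 else sys$K
  Kd <- as.matrix(Kfull[fr, fr, drop = FALSE])
  Cd <- as.matrix(sys$C[fr, fr, drop = FALSE])
  Md <- sys$M[fr]
  dloc <- match(out_dofs, fr)
  if (any(is.na(dloc))) stop("harmonic_response: requested dof is fixed")
  mag <- numeric(length(freqs))
  ph <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    w <- 2 * pi * freqs[i]
    A <- Kd + 1i * w * Cd - w^2 * diag(Md, nrow = length(Md))
    u <- tryCatch(solve(A, f[fr] + 0i),
                  error = function(e) stop(
                    "harmonic_response: singular harmonic system at ",
                    freqs[i], " Hz (unconstrained free modes?)"))
    mag[i] <- Mod(sqrt(sum(u[dloc] * Conj(u[dloc]))))
    ph[i] <- Arg(u[dloc[length(dloc)]])
  }
  list(magnitude = mag, phase = ph)
}

landmark_nodes_sub <- function(scene, name, bodies) {
  lm <- scene$landmarks[[name]]
  nn <- vapply(scene$bodies[bodies], function(b) nrow(b$mesh$nodes), 1L)
  off <- cumsum(c(0L, nn[-length(nn)])); names(off) <- bodies
  if (!(lm$body %in% bodies)) stop("landmark body not in assembled system")
  off[[lm$body]] + lm$nodes
}

# area-weighted pressure load along membrane normals (full dof vector)
membrane_pressure_load <- function(scene, sys, bodies, pressure) {
  f <- numeric(sys$ndof)
  if (!("tympanic_membrane" %in% bodies)) return(f)
  b <- scene$bodies$tympanic_membrane
  o <- sys$offsets[["tympanic_membrane"]]
  tris <- b$mesh$triangles[b$active, , drop = FALSE]
  p1 <- b$mesh$nodes[tris[, 1], , drop = FALSE]
  p2 <- b$mesh$nodes[tris[, 2], , drop = FALSE]
  p3 <- b$mesh$nodes[tris[, 3], , drop = FALSE]
  nx <- (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2])
  ny <- (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3])
  nz <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  # n/2 is area-weighted normal; pressure force = p * A * n_hat = p * n/2
  for (a in 1:3) {
    ids <- 3L * (o + tris[, a]) - 2L
    fx <- pressure * nx / 6; fy <- pressure * ny / 6; fz <- pressure * nz / 6
    for (k in seq_along(ids)) {
      f[ids[k]] <- f[ids[k]] + fx[k]
      f[ids[k] + 1L] <- f[ids[k] + 1L] + fy[k]
      f[ids[k] + 2L] <- f[ids[k] + 2L] + fz[k]
    }
  }
  f
}

#' Static pressure test
#'
#' Static solve `K u = f` under a uniform pressure on the tympanic membrane,
#' in the nominal or a pathological configuration (`otosclerotic = TRUE`
#' stiffens the annular-ligament springs to emulate footplate fixation).
#' Displacements flip sign exactly with the pressure sign (linearity).
#'
#' @param scene an `otosim_scene`.
#' @param pressure static pressure (Pa).
#' @param otosclerotic stiffen the annular ligament by `fixation_factor`.
#' @param fixation_factor multiplier on ligament stiffness for the
#'   pathological case (default 1000).
#' @param method `"direct"` sparse solve or `"cg"` conjugate gradients.
#' @param bodies bodies to include (default: the ossicular chain).
#' @return list with `u` (full displacement vector, m), `peak_membrane_mm`,
#'   `peak_ossicle_mm`.
#' @export
static_pressure_test <- function(scene, pressure, otosclerotic = FALSE,
                                 fixation_factor = 1000,
                                 method = c("direct", "cg"),
                                 bodies = c("footplate", "superstructure",
                                            "incus", "malleus",
                                            "tympanic_membrane")) {
  method <- match.arg(method)
  if (!is.finite(pressure)) stop("static_pressure_test: pressure must be finite")
  if (otosclerotic) {
    lig <- is.na(scene$springs$body_b) & scene$springs$body_a == "footplate"
    scene$springs$stiffness[lig] <- scene$springs$stiffness[lig] * fixation_factor
  }
  bodies <- intersect(bodies, names(scene$bodies))
  sys <- assemble_system(scene, bodies, corotational = FALSE)
  f <- membrane_pressure_load(scene, sys, bodies, pressure)
  fr <- sys$free_idx
  Kff <- sys$K[fr, fr]
  u <- numeric(sys$ndof)
  if (method == "direct") {
    u[fr] <- tryCatch(as.numeric(Matrix::solve(Kff, f[fr])),
                      error = function(e) stop(
                        "static_pressure_test: singular stiffness ",
                        "(unconstrained body?)"))
  } else {
    u[fr] <- cg_solve(Kff, f[fr], tol = 1e-12)
  }
  U <- matrix(u, ncol = 3, byrow = TRUE)
  mags <- sqrt(rowSums(U^2))
  nn <- vapply(scene$bodies[bodies], function(b) nrow(b$mesh$nodes), 1L)
  memb <- which(rep(names(nn), nn) == "tympanic_membrane")
  list(u = u,
       peak_membrane_mm = if (length(memb)) max(mags[memb]) * 1e3 else 0,
       peak_ossicle_mm = if (length(memb) < length(mags))
         max(mags[-memb]) * 1e3 else 0)
}

# Jacobi-preconditioned conjugate gradients on an SPD sparse matrix; the
# diagonal scaling tames the huge stiffness contrast between bone elements
# and ligament springs
cg_solve <- function(A, b, tol = 1e-14, maxit = 50000) {
  n <- length(b)
  x <- numeric(n)
  Minv <- 1 / Matrix::diag(A)
  Minv[!is.finite(Minv)] <- 1
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b * b))
  if (b2 == 0) return(x)
  for (i in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) < tol * b2) break
    z <- Minv * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  x
}

#' Force functional of a contact-force trace
#'
#' `F(t) = mu * df/dt + lambda * integral_0^t f dtau`, with the derivative by
#' central differences (one-sided at the ends) and the integral by the
#' trapezoidal rule. The scalar summary is the peak `max_t |F(t)|`; the full
#' trace is returned so other reductions can be applied.
#'
#' @param trace data frame with columns `t` (s, strictly increasing) and `f`
#'   (N), or a `force_trace`-like object.
#' @param mu weight of the force rate (s).
#' @param lambda weight of the force impulse (1/s).
#' @return list with `F` (scalar peak), `trace` (data frame `t, dfdt, integral,
#'   Ft`).
#' @export
force_functional <- function(trace, mu = 1, lambda = 1) {
  tr <- as.data.frame(trace)
  if (nrow(tr) < 2) stop("force_functional: need at least 2 samples")
  t <- tr$t; f <- tr$f
  if (any(diff(t) <= 0)) stop("force_functional: time must be strictly increasing")
  n <- length(t)
  dfdt <- numeric(n)
  dfdt[1] <- (f[2] - f[1]) / (t[2] - t[1])
  dfdt[n] <- (f[n] - f[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) dfdt[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  integ <- c(0, cumsum((f[-1] + f[-n]) / 2 * diff(t)))
  Ft <- mu * dfdt + lambda * integ
  list(F = max(abs(Ft)), trace = data.frame(t = t, dfdt = dfdt,
                                            integral = integ, Ft = Ft))
}

#' Score weights
#'
#' Constants of the composite quality score and the force functional. The
#' score inputs are normalized by the `ref_*` reference values so that the
#' four terms are commensurable; all constants default to 1.
#'
#' @param alpha,beta,gamma,delta score constants.
#' @param mu,lambda force-functional constants.
#' @param ref_S,ref_F,ref_VF reference scales for distance (mm), force
#'   functional and obstruction time (s).
#' @export
score_weights <- function(alpha = 1, beta = 1, gamma = 1, delta = 1,
                          mu = 1, lambda = 1,
                          ref_S = 1, ref_F = 1, ref_VF = 1) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
            mu = mu, lambda = lambda, ref_S = ref_S, ref_F = ref_F,
            ref_VF = ref_VF)
  if (any(!is.finite(unlist(w)))) stop("score_weights: non-finite weight")
  w
}

#' Composite procedure-quality score
#'
#' `E = alpha/S + beta/F + gamma/VF + delta * (TF_after / TF_before)`, where
#' `S` is the distance to the expert-defined optimal position, `F` the force
#' functional, `VF` the visual obstruction time, and the transfer-function
#' ratio is the frequency-averaged magnitude ratio on identical frequency
#' grids. Higher is better: the score decreases with S, F and VF and
#' increases with the preserved transfer function. A zero S, F or VF leaves
#' its reciprocal term out (with a message), since the limit is undefined.
#'
#' @param S distance to optimal position (mm, normalized by `ref_S`).
#' @param F force functional output (normalized by `ref_F`).
#' @param VF visual obstruction time (s, normalized by `ref_VF`).
#' @param tf_before,tf_after `tf_result`s on the same frequency grid.
#' @param weights [score_weights()].
#' @return scalar score E (dimensionless).
#' @export
quality_score <- function(S, F, VF, tf_before, tf_after,
                          weights = score_weights()) {
  if (!isTRUE(all.equal(tf_before$freqs, tf_after$freqs)))
    stop("quality_score: transfer functions on different frequency grids")
  ratio <- mean(tf_after$magnitude / tf_before$magnitude)
  w <- weights
  term <- function(coef, val, ref, name) {
    if (val < 0) stop("quality_score: ", name, " must be >= 0")
    if (val == 0) {
      message("quality_score: ", name, " = 0; reciprocal term omitted")
      return(0)
    }
    coef / (val / ref)
  }
  term(w$alpha, S, w$ref_S, "S") + term(w$beta, F, w$ref_F, "F") +
    term(w$gamma, VF, w$ref_VF, "VF") + w$delta * ratio
}
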