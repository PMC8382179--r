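# Assumed-modes (Rayleigh-Ritz) basis for a Kirchhoff plate clamped along the
# wing-base edge and free elsewhere. Trial functions are separable products of
# clamped-free beam functions along the span and {rigid translation, rigid
# rotation, free-free elastic} beam functions along the chord; the rigid
# chordwise rotation carries the twisting mode that body rotation excites.

# Clamped-free beam eigenvalue parameters (lambda_j from cos l cosh l = -1).
.cf_lambda <- c(1.87510407, 4.69409113, 7.85475744, 10.99554073,
                14.13716839, 17.27875953)
# Free-free elastic beam parameters (cos m cosh m = 1, excluding rigid modes).
.ff_mu <- c(4.73004074, 7.85320462, 10.99560784, 14.13716549)

# Clamped-free beam function and derivatives on xi in [0, 1].
beam_cf <- function(xi, j) {
  l <- .cf_lambda[j]
  sig <- (sinh(l) - sin(l)) / (cosh(l) + cos(l))
  list(
    f  = cosh(l * xi) - cos(l * xi) - sig * (sinh(l * xi) - sin(l * xi)),
    d1 = l * (sinh(l * xi) + sin(l * xi) - sig * (cosh(l * xi) - cos(l * xi))),
    d2 = l^2 * (cosh(l * xi) + cos(l * xi) - sig * (sinh(l * xi) + sin(l * xi))))
}

# Chordwise family: rigid translation, rigid rotation (normalized Legendre),
# then free-free elastic beam functions.
beam_chord <- function(eta, b) {
  if (b == 1) {
    list(f = rep(1, length(eta)), d1 = rep(0, length(eta)), d2 = rep(0, length(eta)))
  } else if (b == 2) {
    list(f = sqrt(3) * (2 * eta - 1), d1 = rep(2 * sqrt(3), length(eta)),
         d2 = rep(0, length(eta)))
  } else {
    m <- .ff_mu[b - 2]
    sig <- (cosh(m) - cos(m)) / (sinh(m) - sin(m))
    list(
      f  = cosh(m * eta) + cos(m * eta) - sig * (sinh(m * eta) + sin(m * eta)),
      d1 = m * (sinh(m * eta) - sin(m * eta) - sig * (cosh(m * eta) + cos(m * eta))),
      d2 = m^2 * (cosh(m * eta) - cos(m * eta) - sig * (sinh(m * eta) - sin(m * eta))))
  }
}

# Simpson quadrature weights on a uniform grid with an odd number of points.
.simpson_w <- function(n, h) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

# One-dimensional integral tables for a list of {f, d1, d2} evaluated on a
# common quadrature grid.
.mode_tables <- function(fun, n_modes, nq = 801) {
  xi <- seq(0, 1, length.out = nq)
  w <- .simpson_w(nq, xi[2] - xi[1])
  F0 <- sapply(seq_len(n_modes), function(j) fun(xi, j)$f)
  F1 <- sapply(seq_len(n_modes), function(j) fun(xi, j)$d1)
  F2 <- sapply(seq_len(n_modes), function(j) fun(xi, j)$d2)
  # normalize to unit L2 norm on [0, 1]
  nrm <- sqrt(colSums(w * F0^2))
  F0 <- sweep(F0, 2, nrm, "/"); F1 <- sweep(F1, 2, nrm, "/"); F2 <- sweep(F2, 2, nrm, "/")
  list(
    xi = xi, w = w, F0 = F0, F1 = F1, F2 = F2,
    I00 = crossprod(F0, w * F0),     # int f_a f_b
    I11 = crossprod(F1, w * F1),     # int f'_a f'_b
    I22 = crossprod(F2, w * F2),     # int f''_a f''_b
    I20 = crossprod(F2, w * F0),     # int f''_a f_b (row a, col b)
    J0  = colSums(w * F0),           # int f_a
    J1  = colSums(w * xi * F0),      # int xi f_a
    JG  = crossprod(F1, (w * (1 - xi^2) / 2) * F1))  # span-tension geometric term
  }

.plate_cache <- new.env(parent = emptyenv())

# Assemble modal mass, stiffness, damping, geometric-stiffness matrices and
# forcing vectors for a given wing. `stiffness_multiplier` scales the
# flat-plate bending rigidity to the effective (measured) flexural stiffness.
# Assemblies are cached per parameter set (sweeps reuse them heavily).
plate_model <- function(wing, n_span = 4, n_chord = 3,
                        stiffness_multiplier = NULL) {
  key <- paste(wing$youngs_modulus, wing$span, wing$chord, wing$thickness,
               wing$material_density, wing$poisson_ratio, wing$damping_ratio,
               n_span, n_chord,
               if (is.null(stiffness_multiplier)) "auto" else stiffness_multiplier,
               sep = "|")
  cached <- .plate_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- .plate_model_build(wing, n_span, n_chord, stiffness_multiplier)
  .plate_cache[[key]] <- out
  out
}

.plate_model_build <- function(wing, n_span = 4, n_chord = 3,
                               stiffness_multiplier = NULL) {
  if (n_span > length(.cf_lambda) || n_chord > length(.ff_mu) + 2) {
    abort("requested modal basis exceeds the tabulated beam functions")
  }
  L <- wing$span; cc <- wing$chord; h <- wing$thickness
  nu <- wing$poisson_ratio; rho_h <- wing$material_density * h
  D_flat <- wing$youngs_modulus * h^3 / (12 * (1 - nu^2))
  if (is.null(stiffness_multiplier)) {
    # Calibrated so the spanwise flexural stiffness D_x * c equals the
    # measured 1.5e-4 N m^2 at the 3 GPa reference wing.
    D_ref <- 3e9 * h^3 / (12 * (1 - nu^2))
    stiffness_multiplier <- (1.5e-4 / cc) / D_ref
  }
  # Orthotropic rigidities: the measured spanwise flexural stiffness is
  # vein-dominated and applies to spanwise bending only; chordwise bending
  # and torsion are membrane-controlled and keep the flat-plate scale
  # (chordwise flexural stiffness of hawkmoth wings is 1-2 orders below
  # spanwise).
  Dx <- D_flat * stiffness_multiplier
  Dy <- D_flat
  D1 <- nu * Dy
  Dxy <- Dy * (1 - nu) / 2

  TX <- .mode_tables(beam_cf, n_span)
  TY <- .mode_tables(beam_chord, n_chord)

  m <- n_span * n_chord
  idx <- expand.grid(b = seq_len(n_chord), a = seq_len(n_span))  # chord fastest
  A <- idx$a; B <- idx$b

  K <- matrix(0, m, m); M <- matrix(0, m, m); G <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    a <- A[i]; ap <- A[j]; b <- B[i]; bp <- B[j]
    K[i, j] <-
      Dx * (cc / L^3) * TX$I22[a, ap] * TY$I00[b, bp] +
      Dy * (L / cc^3) * TX$I00[a, ap] * TY$I22[b, bp] +
      (D1 / (L * cc)) * (TX$I20[a, ap] * TY$I20[bp, b] +
                         TX$I20[ap, a] * TY$I20[b, bp]) +
      (4 * Dxy / (L * cc)) * TX$I11[a, ap] * TY$I11[b, bp]
    M[i, j] <- rho_h * L * cc * TX$I00[a, ap] * TY$I00[b, bp]
    G[i, j] <- rho_h * L * cc * TX$JG[a, ap] * TY$I00[b, bp]
  }
  K <- (K + t(K)) / 2; M <- (M + t(M)) / 2; G <- (G + t(G)) / 2

  # Moment arms: flapping acts about the spanwise root (x = 0); the
  # transverse body axes pass through the mid-chord line, so
  # rotation-induced chordwise loads enter as a pure torsional couple
  # (arm y - c/2).
  Px <- rho_h * L^2 * cc * TX$J1[A] * TY$J0[B]
  Py <- rho_h * L * cc^2 * TX$J0[A] * (TY$J1[B] - 0.5 * TY$J0[B])

  # modal damping via the generalized eigenproblem K v = om^2 M v
  Lc <- t(chol(M)); Li <- solve(Lc)
  Asym <- Li %*% K %*% t(Li); Asym <- (Asym + t(Asym)) / 2
  eg <- eigen(Asym, symmetric = TRUE)
  om <- sqrt(pmax(eg$values, 0))
  Cd <- Lc %*% eg$vectors %*% diag(2 * wing$damping_ratio * om, m) %*%
    t(eg$vectors) %*% t(Lc)

  list(M = M, Minv = solve(M), K = K, C = Cd, G = G, Px = Px, Py = Py,
       n_span = n_span, n_chord = n_chord, A = A, B = B, TX = TX, TY = TY,
       Dx = Dx, Dy = Dy, rho_h = rho_h, freqs_hz = om / (2 * pi),
       stiffness_multiplier = stiffness_multiplier)
}

# Surface normal strain mode shapes at the grid nodes (n_locations x m).
# Bending part: -(h/2) d2w/dx2 (spanwise) or -(h/2) d2w/dy2 (chordwise).
# Also returns the slope shapes dw/dx (or dw/dy) used for the quadratic
# membrane (von Karman) strain term (1/2)(dw/dx)^2, which dominates near the
# wing tip where bending curvature vanishes but slopes are maximal.
strain_shapes <- function(model, wing, grid, direction = c("spanwise", "chordwise")) {
  direction <- match.arg(direction)
  co <- grid_coordinates(grid)
  h <- wing$thickness; L <- wing$span; cc <- wing$chord
  m <- length(model$A)
  S <- matrix(0, nrow(co), m)
  Dsl <- matrix(0, nrow(co), m)
  for (i in seq_len(m)) {
    fx <- beam_cf(co$span_frac, model$A[i])
    fy <- beam_chord(co$chord_frac, model$B[i])
    # renormalize consistently with .mode_tables
    nx <- sqrt(sum(model$TX$w * beam_cf(model$TX$xi, model$A[i])$f^2))
    ny <- sqrt(sum(model$TY$w * beam_chord(model$TY$xi, model$B[i])$f^2))
    if (direction == "spanwise") {
      S[, i] <- -(h / 2) * (fx$d2 / nx) * (fy$f / ny) / L^2
      Dsl[, i] <- (fx$d1 / nx) * (fy$f / ny) / L
    } else {
      S[, i] <- -(h / 2) * (fx$f / nx) * (fy$d2 / ny) / cc^2
      Dsl[, i] <- (fx$f / nx) * (fy$d1 / ny) / cc
    }
  }
  list(bend = S, slope = Dsl)
}

# Augment modal coordinates and shapes with the pairwise products that carry
# the quadratic membrane strain: strain(t, loc) = q S_bend' + 1/2 (q Dsl')^2,
# rewritten exactly as an augmented low-rank product so filtering and
# encoding keep operating on (time x modes) factors.
augment_strain_rank <- function(q, shapes) {
  m <- ncol(q)
  pairs <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  qq <- matrix(0, nrow(q), nrow(pairs))
  S2 <- matrix(0, nrow(shapes$slope), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    coef <- if (i == j) 0.5 else 1
    qq[, k] <- coef * q[, i] * q[, j]
    S2[, k] <- shapes$slope[, i] * shapes$slope[, j]
  }
  list(q = cbind(q, qq), S = cbind(shapes$bend, S2), m_linear = m)
}
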