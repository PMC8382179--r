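# Sparse sensor placement optimization for classification (SSPOC):
# (1) PCA of the standardized training features -> orthonormal basis Psi,
# (2) LDA in the subspace -> discriminant projection w,
# (3) elastic-net recovery of a sparse full-space weight vector s with
#     Psi' s = w (two-class) or |Psi' s - w| <= eps elementwise (multi-class),
# solved by a Douglas-Rachford proximal iteration (both proximal maps are
# closed-form because Psi has orthonormal columns).

#' Fit the low-dimensional discriminant subspace
#'
#' Standardizes the training features per sensor (z-score; zero-variance
#' sensors get unit scale), takes the top-`m` principal components as the
#' basis `Psi`, and fits a linear discriminant analysis on the projected data
#' to obtain the projection `w` that maximally separates the classes.
#'
#' @param features A labelled `spike_features` (see [bind_features()]), or a
#'   numeric matrix with `labels` supplied.
#' @param params An [sspoc_params()].
#' @param labels Class labels when `features` is a bare matrix.
#' @param mask Optional integer vector of candidate location indices; sensors
#'   outside the mask are excluded from the fit and receive zero weight.
#' @return A `subspace_model` with elements `Psi` (n x m, orthonormal
#'   columns), `w` (m x n_discriminants), standardization `center`/`scale`,
#'   `mask`, and the LDA separation statistic.
#' @export
fit_subspace <- function(features, params = sspoc_params(), labels = NULL,
                         mask = NULL) {
  X <- if (inherits(features, "spike_features")) features$features else as.matrix(features)
  y <- if (inherits(features, "spike_features")) features$label else labels
  if (is.null(y)) abort("class labels are required")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) abort("at least two classes are required")
  if (nrow(X) < params$m) abort("fewer observations than subspace dimensions")
  n_all <- ncol(X)
  if (!is.null(mask)) X <- X[, mask, drop = FALSE]

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  m <- min(params$m, ncol(Xs), nrow(Xs) - 1)
  Psi <- .pca_basis(Xs, m)

  Z <- Xs %*% Psi
  ld <- lda_directions(Z, y, ridge = 1e-6)

  structure(
    list(Psi = Psi, w = ld$W, center = ctr, scale = scl, mask = mask,
         n_locations = n_all, m = m, classes = levels(y),
         separation = ld$separation),
    class = "subspace_model")
}

# Top-m principal directions of a centered matrix, via the thin side of the
# eigenproblem; large problems use a seeded randomized range finder with two
# power iterations (ample for the leading components).
.pca_basis <- function(Xs, m) {
  n_obs <- nrow(Xs); n_var <- ncol(Xs)
  if (min(n_obs, n_var) > 600) {
    q <- min(m + 7L, n_var)
    Q <- with_seed(104729L, matrix(rnorm(n_var * q), n_var, q))
    for (i in 1:3) {
      Z <- crossprod(Xs, Xs %*% Q)
      Q <- qr.Q(qr(Z))
    }
    B <- crossprod(Xs %*% Q)  # q x q Gram in the candidate range
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    Psi <- Q %*% eg$vectors[, seq_len(m), drop = FALSE]
    return(qr.Q(qr(Psi)))
  }
  if (n_obs < n_var) {
    Gm <- tcrossprod(Xs)
    eg <- eigen(Gm, symmetric = TRUE)
    keep <- seq_len(m)
    ev <- pmax(eg$values[keep], 1e-300)
    Psi <- crossprod(Xs, eg$vectors[, keep, drop = FALSE])
    Psi <- sweep(Psi, 2, sqrt(ev), "/")
  } else {
    Cm <- crossprod(Xs)
    eg <- eigen(Cm, symmetric = TRUE)
    Psi <- eg$vectors[, seq_len(m), drop = FALSE]
  }
  # re-orthonormalize against numerical drift
  qr.Q(qr(Psi))
}

# LDA discriminant directions with ridge-regularized pooled within-class
# scatter; returns up to (classes - 1) unit-norm columns and the
# between/within separation statistic along the first direction.
lda_directions <- function(Z, y, ridge = 1e-6) {
  Z <- as.matrix(Z)
  classes <- levels(y)
  p <- ncol(Z)
  mu <- colMeans(Z)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in classes) {
    Zc <- Z[y == cl, , drop = FALSE]
    mc <- colMeans(Zc)
    d <- sweep(Zc, 2, mc)
    Sw <- Sw + crossprod(d)
    Sb <- Sb + nrow(Zc) * tcrossprod(mc - mu)
  }
  Sw <- Sw / nrow(Z)
  Sb <- Sb / nrow(Z)
  Swr <- Sw + (ridge * mean(diag(Sw)) + 1e-12) * diag(p)
  if (length(classes) == 2) {
    mdiff <- colMeans(Z[y == classes[1], , drop = FALSE]) -
      colMeans(Z[y == classes[2], , drop = FALSE])
    w <- solve(Swr, mdiff)
    nrm <- sqrt(sum(w^2))
    if (nrm < 1e-300) w <- c(1, rep(0, p - 1)) else w <- w / nrm
    W <- matrix(w, ncol = 1)
  } else {
    M <- solve(Swr, Sb)
    eg <- eigen(M)
    k <- length(classes) - 1
    W <- Re(eg$vectors[, seq_len(k), drop = FALSE])
    W <- sweep(W, 2, pmax(sqrt(colSums(W^2)), 1e-300), "/")
  }
  sep <- as.numeric(t(W[, 1]) %*% Sb %*% W[, 1]) /
    as.numeric(t(W[, 1]) %*% Swr %*% W[, 1])
  list(W = W, separation = sep)
}

# Proximal map of t * (lam ||.||_1 + (1 - lam) ||.||_2): elementwise soft
# threshold followed by block (Euclidean-norm) shrinkage.
.prox_en <- function(v, t, lam) {
  s <- sign(v) * pmax(abs(v) - t * lam, 0)
  ns <- sqrt(sum(s^2))
  if (ns <= t * (1 - lam)) return(0 * s)
  s * (1 - t * (1 - lam) / ns)
}

# Projection onto {s : |Psi' s - w| <= eps elementwise} (eps = 0 gives the
# equality constraint). Exact because Psi has orthonormal columns.
.proj_constraint <- function(v, Psi, w, eps) {
  a <- as.vector(crossprod(Psi, v))
  a_cl <- pmin(pmax(a, w - eps), w + eps)
  v + Psi %*% (a_cl - a)
}

# Douglas-Rachford iteration for min lam||s||_1 + (1-lam)||s||_2 subject to
# the (boxed) subspace constraint.
solve_en <- function(Psi, w, lam, eps = 0, step = NULL, max_iter = 2000,
                     tol = 1e-10) {
  w <- as.vector(w)
  if (is.null(step)) step <- 2 * max(max(abs(w)), 1e-8)
  y <- Psi %*% w
  p <- y
  for (it in seq_len(max_iter)) {
    p <- .proj_constraint(y, Psi, w, eps)
    z <- .prox_en(as.vector(2 * p - y), step, lam)
    delta <- z - p
    y <- y + delta
    if (max(abs(delta)) < tol * max(1, max(abs(p)))) break
  }
  s <- as.vector(.proj_constraint(z, Psi, w, eps))
  list(s = s, iterations = it,
       residual = max(abs(as.vector(crossprod(Psi, s)) - w)) - eps)
}

#' Solve for sparse sensor weights (two-class task)
#'
#' Solves `argmin_s lam ||s||_1 + (1 - lam) ||s||_2` subject to
#' `Psi' s = w`: the sparsest set of sensor weights whose projection onto the
#' PCA basis reconstructs the discriminant direction.
#'
#' @param model A [fit_subspace()] result with two classes.
#' @param params An [sspoc_params()].
#' @return A `sensor_weights` object: full-length weight vector `s` (zeros
#'   outside any mask), `selected` top-k locations, constraint residual.
#' @export
solve_sensors_2class <- function(model, params = sspoc_params()) {
  if (length(model$classes) != 2) abort("two-class model required")
  sol <- solve_en(model$Psi, model$w[, 1], params$lam, eps = 0)
  if (sol$residual > 1e-6) {
    abort(sprintf("elastic-net solve failed: constraint residual %.3g", sol$residual))
  }
  new_sensor_weights(matrix(sol$s, ncol = 1), model, params, sol$residual,
                     sol$iterations)
}

#' Solve for sparse sensor weights (multi-class task)
#'
#' Relaxed program with elementwise constraint `|Psi' s - w| <= eps`, solved
#' columnwise over the discriminant directions; sensors are ranked by the
#' row-wise Euclidean norm of the weight matrix.
#'
#' @param model A [fit_subspace()] result (any number of classes >= 2).
#' @param params An [sspoc_params()].
#' @return A `sensor_weights` object.
#' @export
solve_sensors_multiclass <- function(model, params = sspoc_params()) {
  cols <- ncol(model$w)
  Smat <- matrix(0, nrow(model$Psi), cols)
  resid <- its <- numeric(cols)
  for (j in seq_len(cols)) {
    sol <- solve_en(model$Psi, model$w[, j], params$lam, eps = params$eps)
    if (sol$residual > 1e-6) {
      abort(sprintf("elastic-net solve failed on column %d: residual %.3g", j, sol$residual))
    }
    Smat[, j] <- sol$s; resid[j] <- sol$residual; its[j] <- sol$iterations
  }
  new_sensor_weights(Smat, model, params, max(resid), max(its))
}

new_sensor_weights <- function(Smat, model, params, residual, iterations) {
  agg_masked <- sqrt(rowSums(Smat^2))
  s_full <- matrix(0, model$n_locations, ncol(Smat))
  agg <- numeric(model$n_locations)
  idx <- if (is.null(model$mask)) seq_len(model$n_locations) else model$mask
  s_full[idx, ] <- Smat
  agg[idx] <- agg_masked
  sel <- top_k(agg, params$k)
  structure(
    list(s = s_full, aggregate = agg, selected = sel, k = params$k,
         residual = residual, iterations = iterations,
         classes = model$classes, mask = model$mask),
    class = "sensor_weights")
}

#' Top-k sensors by absolute weight
#'
#' @param weights A `sensor_weights` object or a numeric weight vector.
#' @param k Number of sensors to keep.
#' @return Integer indices of the k largest |weights|, in decreasing weight
#'   order; ties broken deterministically toward the lower grid index.
#' @export
top_k <- function(weights, k = 10) {
  w <- if (inherits(weights, "sensor_weights")) weights$aggregate else abs(as.numeric(weights))
  stopifnot(k >= 1, k <= length(w))
  if (all(w == 0)) abort("all sensor weights are zero; no informative sensors")
  ord <- order(-w, seq_along(w))
  ord[seq_len(k)]
}

#' Number of effectively nonzero weights
#'
#' @param weights A `sensor_weights` object.
#' @param tol Near-zero tolerance relative to the largest |weight|.
#' @return Count of entries above `tol * max`.
#' @export
n_active_sensors <- function(weights, tol = 1e-4) {
  sum(weights$aggregate > tol * max(weights$aggregate))
}

#' @export
print.sensor_weights <- function(x, ...) {
  cat(sprintf("<sensor_weights> %d locations, %d above tolerance, top-%d selected; constraint residual %.2g\n",
              length(x$aggregate), n_active_sensors(x), x$k, max(x$residual, 0)))
  invisible(x)
}

#' @export
tidy.sensor_weights <- function(x, grid = sensor_grid(), ...) {
  co <- grid_coordinates(grid)
  dplyr::mutate(co,
                weight = x$aggregate,
                selected = .data$location %in% x$selected)
}
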