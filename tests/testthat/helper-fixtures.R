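# Shared miniature fixtures: everything is generated in code, seeded, and
# small enough that the whole suite stays fast.

small_grid <- function() sensor_grid(11, 6)

# Labelled features from a two-class surrogate with a given twist-amplitude
# pair; the workhorse for encoder/selection/evaluation tests.
surrogate_features <- function(twist_amps = c(0.05, 0.8), noise = 0.02,
                               seed = 1, duration = 0.6, n_repeats = 5,
                               grid = small_grid(), beta = 0.4) {
  enc <- encoder_params(beta = beta)
  nc <- length(twist_amps)
  seeds <- wingsense:::derive_seeds(seed, 2 * nc)
  fields <- lapply(seq_len(nc), function(i) {
    surrogate_strain(grid, list(twist_amp = twist_amps[i], noise = noise),
                     seed = seeds[i], duration = duration)
  })
  enc$norm_constant <- compute_norm_constant(fields[[1]], enc)
  feats <- lapply(seq_len(nc), function(i) {
    encode_strain(fields[[i]], enc, n_repeats = n_repeats, seed = seeds[nc + i])
  })
  labels <- if (nc == 2) c("none", "rotation") else paste0("class", seq_len(nc))
  bind_features(feats, labels)
}

# A detection task whose data come from the surrogate generator (no plate
# solve), for exercising the selection/evaluation pipeline quickly.
surrogate_task <- function(twist_amps = c(0.05, 0.8), noise = 0.02,
                           k = 5, deterministic = FALSE) {
  detection_task(
    axis = "yaw", sspoc = sspoc_params(k = k),
    data_fn = function(task, seed) {
      surrogate_features(twist_amps, noise,
                         seed = if (deterministic) 1L else seed)
    })
}

# Quick noise-free plate simulation at reduced duration.
quiet_sim <- function(axis = "none", stiffness_factor = 1, duration = 0.4,
                      seed = 1, ...) {
  simulate_strain(
    wing_params(stiffness_factor = stiffness_factor),
    flapping_kinematics(flapping_noise_frac = 0),
    rotation_condition(axis, rotation_noise_frac = 0),
    duration = duration, seed = seed, ...)
}

# Zooming dense-grid minimizer of lam||s||_1 + (1-lam)||s||_2 over the
# feasible affine set {Psi w + N z}: the independent oracle for small
# instances.
en_objective <- function(s, lam) lam * sum(abs(s)) + (1 - lam) * sqrt(sum(s^2))

brute_force_en <- function(Psi, w, lam, radius = NULL, levels = 4, npts = 41) {
  n <- nrow(Psi)
  Nn <- qr.Q(qr(cbind(Psi, matrix(rnorm(n * n), n))))[, (ncol(Psi) + 1):n, drop = FALSE]
  base <- as.vector(Psi %*% w)
  d <- ncol(Nn)
  stopifnot(d == 2)  # oracle implemented for 2-dim feasible sets
  if (is.null(radius)) radius <- 2 * sqrt(sum(base^2)) + 1
  ctr <- c(0, 0)
  for (lev in seq_len(levels)) {
    zs <- seq(-radius, radius, length.out = npts)
    gr <- as.matrix(expand.grid(z1 = zs + ctr[1], z2 = zs + ctr[2]))
    obj <- apply(gr, 1, function(z) en_objective(base + Nn %*% z, lam))
    i <- which.min(obj)
    ctr <- gr[i, ]
    radius <- radius * 2.5 / npts
  }
  # final simplex polish from the best grid point
  op <- stats::optim(ctr, function(z) en_objective(base + Nn %*% z, lam),
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 2000))
  list(objective = op$value, z = op$par)
}
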