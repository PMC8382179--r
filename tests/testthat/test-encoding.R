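# Linear-nonlinear spiking encoder.

test_that("filter kernel matches its closed form", {
  h <- filter_kernel(encoder_params(), dt = 1e-4)
  lags <- attr(h, "lags_ms")
  # peak value 1 at lag -tau
  expect_equal(max(h), 1, tolerance = 1e-12)
  expect_equal(lags[which.max(h)], -5)
  # value at t = 0: cos(5) exp(-25/16)
  expect_equal(h[1], cos(5) * exp(-25 / 16), tolerance = 1e-12)
  # support ends where the envelope is below e^-9
  expect_lt(abs(h[length(h)]), exp(-9) + 1e-12)
  # delta -> 0 collapses the kernel to impulse-like support
  h0 <- filter_kernel(encoder_params(delta = 1e-3), dt = 1e-4)
  expect_lt(sum(abs(h0) > 1e-6), 3)
})

test_that("filtering is linear, causal, and reproduces the impulse response", {
  p <- encoder_params()
  h <- filter_kernel(p, dt = 1e-4)
  x <- matrix(0, 500, 2)
  x[100, 1] <- 1
  g <- filter_strain(x, p, dt = 1e-4)
  # impulse at t0 -> kernel laid out causally from t0
  expect_equal(g[100:270, 1], as.numeric(h), tolerance = 1e-10)
  expect_true(all(g[1:99, 1] == 0))  # causality
  expect_true(all(g[, 2] == 0))      # zero in -> zero out
  # linearity
  expect_equal(filter_strain(3 * x, p, dt = 1e-4), 3 * g, tolerance = 1e-12)
})

test_that("FFT and direct convolution paths agree", {
  h <- filter_kernel(encoder_params(), dt = 1e-4)
  set.seed(4)
  x <- matrix(rnorm(3000 * 50), 3000, 50)      # large: FFT path
  y_fft <- wingsense:::.causal_conv(x, h)
  y_dir <- apply(x, 2, wingsense:::.causal_conv, h = h)  # vector path: direct
  expect_equal(y_fft, y_dir, tolerance = 1e-10)
})

test_that("randomized and exact PCA bases span the same leading subspace", {
  set.seed(9)
  # moderately sized matrix with a clear low-rank structure plus noise
  U <- matrix(rnorm(700 * 3), 700, 3)
  V <- matrix(rnorm(650 * 3), 650, 3)
  X <- U %*% t(V) * 5 + matrix(rnorm(700 * 650), 700, 650)
  Xs <- scale(X, scale = FALSE)
  Psi_r <- wingsense:::.pca_basis(Xs, 3)           # randomized (min dim > 600)
  ev <- eigen(crossprod(Xs), symmetric = TRUE)
  Psi_e <- ev$vectors[, 1:3]
  # captured variance ratio
  var_r <- sum(colSums((Xs %*% Psi_r)^2))
  var_e <- sum(colSums((Xs %*% Psi_e)^2))
  expect_gt(var_r / var_e, 0.999)
  expect_equal(crossprod(Psi_r), diag(3), tolerance = 1e-10)
})

test_that("normalization scales the reference maximum to exactly 1", {
  f <- surrogate_strain(small_grid(), list(twist_amp = 0.2, noise = 0),
                        seed = 1, duration = 0.2)
  p <- encoder_params()
  nc <- compute_norm_constant(f, p)
  p$norm_constant <- nc
  expect_equal(strain_peak(filter_strain(f, p)), 1, tolerance = 1e-10)
  # a weaker field under the same constant stays below 1
  f2 <- f; f2$q <- 0.5 * f$q
  expect_lt(strain_peak(filter_strain(f2, p)), 1)
  # permutation invariance of the constant
  fperm <- f; perm <- rev(seq_len(nrow(f$S))); fperm$S <- f$S[perm, ]
  expect_equal(compute_norm_constant(fperm, p), nc, tolerance = 1e-12)
  # all-zero reference is rejected
  fz <- f; fz$q <- 0 * f$q
  expect_error(compute_norm_constant(fz, p), "zero")
})

test_that("nonlinearity matches its closed forms and monotonicity", {
  p <- encoder_params(beta = 0.2, alpha = 50)
  expect_equal(nonlinearity(0.2, p), 0.5)
  expect_equal(nonlinearity(0.3, p), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_lt(nonlinearity(-100, p), 1e-15)
  g <- seq(0, 0.4, length.out = 101)  # within floating-point resolution of the sigmoid
  expect_true(all(diff(nonlinearity(g, p)) > 0))
  # raising the threshold lowers P(fire) pointwise
  p2 <- encoder_params(beta = 0.4)
  expect_true(all(nonlinearity(g, p2) < nonlinearity(g, p)))
})

test_that("spike generation honours probability and refractoriness", {
  # p = 0: silent
  r0 <- generate_spikes(matrix(0, 400, 2), n_repeats = 3, seed = 1)
  expect_equal(sum(r0$data), 0)
  # p = 1 over one 40 ms wingbeat with 15 ms refractory: spikes at 0, 15, 30 ms
  r1 <- generate_spikes(matrix(1, 400, 1), n_repeats = 2, seed = 1)
  expect_equal(which(r1$data[, 1, 1] == 1), c(1L, 151L, 301L))
  expect_equal(which(r1$data[, 1, 2] == 1), c(1L, 151L, 301L))
  # binomial mean with refractory shorter than one step
  pm <- matrix(0.3, 2000, 1)
  r <- generate_spikes(pm, refractory = 0.1, n_repeats = 20, seed = 7)
  counts <- apply(r$data, 3, sum)
  expect_lt(abs(mean(counts) - 0.3 * 2000),
            3 * sqrt(2000 * 0.3 * 0.7 / 20))
  # refractory invariant on a stochastic raster
  rr <- generate_spikes(matrix(0.2, 1500, 3), n_repeats = 4, seed = 3)
  for (j in 1:3) for (k in 1:4) {
    st <- which(rr$data[, j, k] == 1)
    if (length(st) > 1) expect_true(all(diff(st) >= 150))
  }
})

test_that("first-spike features follow the sentinel and quantization rules", {
  # empty raster -> all-zero features
  r0 <- generate_spikes(matrix(0, 800, 2), n_repeats = 2, seed = 1)
  f0 <- first_spike_features(r0)
  expect_true(all(f0$features == 0))
  expect_equal(dim(f0$features), c(4L, 2L))  # 2 wingbeats x 2 repeats
  # hand-placed spike at 7.3 ms into wingbeat 2
  r <- r0
  r$data[400 + 74, 2, 1] <- 1L   # step index 74 within wingbeat 2 = 7.3 ms
  f <- first_spike_features(r)
  expect_equal(f$features[2, 2], 7.3)
  expect_equal(sum(f$features != 0), 1)
  # all nonzero entries lie on the 0.1 ms grid within (0, 40]
  sf <- surrogate_features(seed = 5)
  nz <- sf$features[sf$features != 0]
  expect_true(all(abs(nz / 0.1 - round(nz / 0.1)) < 1e-9))
  expect_true(all(nz > 0 & nz <= 40))
})

test_that("fast encoding path equals the modular path", {
  f <- surrogate_strain(small_grid(), list(twist_amp = 0.4, noise = 0.02),
                        seed = 2, duration = 0.2)
  p <- encoder_params(beta = 0.3)
  p$norm_constant <- compute_norm_constant(f, p)
  fast <- encode_strain(f, p, n_repeats = 3, seed = 11)
  g <- filter_strain(strain_matrix(f), p, dt = f$dt)
  pr <- nonlinearity(g, p)
  raster <- generate_spikes(pr, refractory = p$refractory, n_repeats = 3,
                            seed = 11, dt = f$dt)
  slow <- first_spike_features(raster, wingbeat_period = 40)
  expect_equal(fast$features, slow$features)
})

test_that("a full-length two-condition data set has 1,500 observations", {
  g <- small_grid()
  enc <- encoder_params(beta = 0.3)
  fields <- lapply(1:2, function(i)
    surrogate_strain(g, list(twist_amp = c(0.05, 0.6)[i]), seed = i,
                     duration = 3))
  enc$norm_constant <- compute_norm_constant(fields[[1]], enc)
  feats <- lapply(1:2, function(i)
    encode_strain(fields[[i]], enc, n_repeats = 10, seed = i))
  all_f <- bind_features(feats, c("none", "rotation"))
  expect_equal(nrow(all_f$features), 1500L)  # 75 wingbeats x 10 repeats x 2
  expect_equal(as.vector(table(all_f$label)), c(750L, 750L))
})

test_that("stronger class separation does not reduce downstream accuracy", {
  accs <- vapply(list(c(0.3, 0.3), c(0.3, 0.5), c(0.3, 0.9)), function(amps) {
    fe <- surrogate_features(amps, noise = 0.02, seed = 4)
    sp <- split_data(fe, 0.9, seed = 1)
    model <- fit_subspace(sp$train, sspoc_params(k = 5))
    w <- solve_sensors_2class(model, sspoc_params(k = 5))
    fit_and_score(sp$train, sp$test, w$selected)$accuracy
  }, 1)
  expect_true(accs[3] >= accs[1] - 0.1)
  expect_gt(accs[3], 0.9)
  expect_lt(abs(accs[1] - 0.5), 0.25)
})
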