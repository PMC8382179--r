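# SSPOC: subspace fit and elastic-net sparse recovery.

test_that("subspace fit recovers a dominant single-axis separation", {
  set.seed(1)
  n <- 20; n_obs <- 200
  # noiseless construction: the only varying coordinate is sensor 7
  X <- matrix(0, n_obs, n)
  y <- factor(rep(c("a", "b"), each = n_obs / 2))
  X[, 7] <- ifelse(y == "a", -1, 1) + rnorm(n_obs, sd = 0.01)
  m <- fit_subspace(X, sspoc_params(m = 3), labels = y)
  expect_gt(abs(m$Psi[7, 1]), 0.99)
  expect_equal(crossprod(m$Psi), diag(3), tolerance = 1e-10)
  # identical class distributions: separation collapses
  m0 <- fit_subspace(matrix(rnorm(400), 100, 4), sspoc_params(m = 2),
                     labels = factor(rep(c("a", "b"), 50)))
  expect_lt(m0$separation, 0.5)
})

test_that("equality-constrained solve matches forced and closed-form cases", {
  # Psi = identity block: constraint forces s = (w, 0)
  n <- 12; m <- 3
  Psi <- rbind(diag(m), matrix(0, n - m, m))
  w <- c(0.8, -0.3, 0.5)
  sol <- wingsense:::solve_en(Psi, w, lam = 0.9)
  expect_equal(as.vector(sol$s), c(w, rep(0, n - m)), tolerance = 1e-7)
  expect_lte(sol$residual, 1e-6)
  # lam = 0: minimum-norm solution Psi w (orthonormal basis)
  set.seed(3)
  Psi2 <- qr.Q(qr(matrix(rnorm(10 * 3), 10)))[, 1:3]
  w2 <- rnorm(3)
  sol2 <- wingsense:::solve_en(Psi2, w2, lam = 0)
  expect_equal(as.vector(sol2$s), as.vector(Psi2 %*% w2), tolerance = 1e-6)
})

test_that("solver attains the dense-grid brute-force optimum on small instances", {
  for (seed in 1:4) {
    set.seed(seed)
    Psi <- qr.Q(qr(matrix(rnorm(8), 4)))  # n = 4, m = 2, null dim 2
    w <- rnorm(2)
    sol <- wingsense:::solve_en(Psi, w, lam = 0.9)
    set.seed(seed + 100)
    bf <- brute_force_en(Psi, w, lam = 0.9)
    expect_lte(en_objective(sol$s, 0.9), bf$objective + 1e-4)
    expect_gte(en_objective(sol$s, 0.9), bf$objective - 1e-4)
  }
})

test_that("constraint residual stays within tolerance on random instances", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(10:60, 1)
    Psi <- qr.Q(qr(matrix(rnorm(n * 3), n)))[, 1:3]
    w <- rnorm(3)
    lam <- runif(1)
    sol <- wingsense:::solve_en(Psi, w, lam = lam)
    expect_lte(max(abs(crossprod(Psi, sol$s) - w)), 1e-6)
  }
})

test_that("multi-class relaxation is consistent with the equality program", {
  set.seed(5)
  Psi <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))[, 1:3]
  w <- rnorm(3)
  # eps -> large: the zero vector is feasible and optimal
  sol_inf <- wingsense:::solve_en(Psi, w, lam = 0.9, eps = 1e6)
  expect_lt(max(abs(sol_inf$s)), 1e-6)
  # eps = 1e-6 recovers the two-class solution
  s_eq <- wingsense:::solve_en(Psi, w, lam = 0.9, eps = 0)$s
  s_rel <- wingsense:::solve_en(Psi, w, lam = 0.9, eps = 1e-6)$s
  expect_equal(as.vector(s_rel), as.vector(s_eq), tolerance = 1e-4)
})

test_that("multi-class selection covers disjoint informative sensor sets", {
  set.seed(9)
  n <- 24; n_obs <- 300
  X <- matrix(rnorm(n_obs * n, sd = 0.05), n_obs, n)
  y <- factor(rep(c("a", "b", "c", "d"), length.out = n_obs))
  X[y == "b", 3] <- X[y == "b", 3] + 1
  X[y == "c", 11] <- X[y == "c", 11] + 1
  X[y == "d", 20] <- X[y == "d", 20] + 1
  model <- fit_subspace(X, sspoc_params(m = 3, k = 6), labels = y)
  wts <- solve_sensors_multiclass(model, sspoc_params(m = 3, k = 6))
  expect_true(all(c(3, 11, 20) %in% wts$selected))
  expect_lte(max(wts$residual, 0), 1e-6)
})

test_that("top_k ranks by magnitude with deterministic tie-breaking", {
  expect_equal(top_k(c(0.9, 0.1, 0, 0.5), 2), c(1L, 4L))
  expect_equal(top_k(c(0.5, 0.9, 0.5, 0.1), 4), c(2L, 1L, 3L, 4L))
  expect_equal(top_k(c(-0.7, 0.7, 0.2), 2), c(1L, 2L))  # abs, lower index first
  expect_error(top_k(rep(0, 5), 2), "zero")
})

test_that("solutions are equivariant under sensor permutation", {
  set.seed(13)
  Psi <- qr.Q(qr(matrix(rnorm(15 * 3), 15)))[, 1:3]
  w <- rnorm(3)
  s <- wingsense:::solve_en(Psi, w, lam = 0.9)$s
  perm <- sample(15)
  s_p <- wingsense:::solve_en(Psi[perm, ], w, lam = 0.9)$s
  expect_equal(as.vector(s_p), as.vector(s[perm]), tolerance = 1e-7)
})

test_that("higher lambda never increases the active sensor count", {
  fe <- surrogate_features(seed = 21)
  sp <- split_data(fe, 0.9, seed = 1)
  counts <- vapply(c(0.1, 0.5, 0.9, 0.99), function(lam) {
    pars <- sspoc_params(lam = lam, k = 5)
    model <- fit_subspace(sp$train, pars)
    n_active_sensors(solve_sensors_2class(model, pars), tol = 1e-3)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("location masks confine selection to the candidate region", {
  fe <- surrogate_features(seed = 8)
  sp <- split_data(fe, 0.9, seed = 1)
  mask <- grid_region(small_grid(), "distal")
  pars <- sspoc_params(k = 5)
  model <- fit_subspace(sp$train, pars, mask = mask)
  wts <- solve_sensors_2class(model, pars)
  expect_true(all(wts$selected %in% mask))
  expect_true(all(wts$aggregate[setdiff(seq_len(66), mask)] == 0))
})

test_that("selection tracks discriminative subsets on small instances (soft oracle)", {
  # The SSPOC objective (subspace reconstruction) differs by design from
  # direct subset search on LDA separation; agreement is expected often but
  # not always, so mismatches are reported rather than failed.
  agree <- 0; trials <- 6
  for (seed in seq_len(trials)) {
    set.seed(seed)
    n <- 8; n_obs <- 120
    X <- matrix(rnorm(n_obs * n, sd = 0.2), n_obs, n)
    y <- factor(rep(c("a", "b"), each = n_obs / 2))
    informative <- sample(n, 2)
    X[, informative] <- X[, informative] + outer(ifelse(y == "a", -1, 1), c(1, 0.8))
    pars <- sspoc_params(m = 2, k = 2)
    model <- fit_subspace(X, pars, labels = y)
    sel <- solve_sensors_2class(model, pars)$selected
    if (setequal(sel, informative)) agree <- agree + 1
  }
  message(sprintf("subset-oracle agreement: %d/%d trials", agree, trials))
  expect_gte(agree, trials / 2)
})
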