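# Train/test splitting and the centroid readout.

fake_features <- function(n_obs = 1500, n_loc = 12, shift = 0, sd = 1,
                          seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_obs * n_loc, sd = sd), n_obs, n_loc)
  y <- factor(rep(c("none", "rot"), each = n_obs / 2))
  X[y == "rot", 1:3] <- X[y == "rot", 1:3] + shift
  out <- wingsense:::new_spike_features(X, n_wb = n_obs / 20, n_reps = 10,
                                        dt_ms = 0.1, period_ms = 40,
                                        label = y)
  out
}

test_that("stratified split gives the documented 1350/150 partition", {
  fe <- fake_features()
  sp <- split_data(fe, 0.9, seed = 3)
  expect_equal(nrow(sp$train$features), 1350L)
  expect_equal(nrow(sp$test$features), 150L)
  expect_equal(as.vector(table(sp$test$label)), c(75L, 75L))
  # deterministic given seed, disjoint by construction
  sp2 <- split_data(fe, 0.9, seed = 3)
  expect_identical(sp$test$features, sp2$test$features)
  sp3 <- split_data(fe, 0.9, seed = 4)
  expect_false(identical(sp$test$features, sp3$test$features))
  expect_error(split_data(fe, 1), "strictly between")
  expect_error(split_data(fe, 0.9999), "absent")
})

test_that("separable classes score perfectly; shuffled labels score at chance", {
  fe <- fake_features(shift = 10, sd = 0.1)
  sp <- split_data(fe, 0.9, seed = 1)
  expect_equal(fit_and_score(sp$train, sp$test, 1:3)$accuracy, 1)
  # label shuffle
  fesh <- fake_features(shift = 10, sd = 0.1, seed = 2)
  fesh$label <- wingsense:::with_seed(7, sample(fesh$label))
  spsh <- split_data(fesh, 0.9, seed = 1)
  acc <- fit_and_score(spsh$train, spsh$test, 1:3)$accuracy
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 150))
})

test_that("accuracy is invariant to affine rescaling of all features", {
  fe <- fake_features(shift = 1.2, seed = 5)
  sp <- split_data(fe, 0.9, seed = 2)
  a1 <- fit_and_score(sp$train, sp$test, 1:6)$accuracy
  sp_scaled <- sp
  sp_scaled$train$features <- sp$train$features * 37 + 11
  sp_scaled$test$features <- sp$test$features * 37 + 11
  a2 <- fit_and_score(sp_scaled$train, sp_scaled$test, 1:6)$accuracy
  expect_equal(a1, a2)
})

test_that("a single fully informative sensor matches the multi-sensor readout", {
  set.seed(6)
  n_obs <- 400
  X <- matrix(rnorm(n_obs * 10, sd = 0.05), n_obs, 10)
  y <- factor(rep(c("none", "rot"), each = n_obs / 2))
  X[, 4] <- X[, 4] + ifelse(y == "rot", 3, 0)
  fe <- wingsense:::new_spike_features(X, n_wb = 40, n_reps = 10,
                                       dt_ms = 0.1, period_ms = 40, label = y)
  sp <- split_data(fe, 0.9, seed = 1)
  expect_equal(fit_and_score(sp$train, sp$test, 4)$accuracy,
               fit_and_score(sp$train, sp$test, 1:10)$accuracy)
})

test_that("fitting uses the training split only (no test leakage)", {
  fe <- fake_features(shift = 1, seed = 9)
  sp <- split_data(fe, 0.9, seed = 4)
  m1 <- fit_subspace(sp$train, sspoc_params())
  # shuffling the test rows must not change anything fit on train
  perm <- wingsense:::with_seed(1, sample(nrow(sp$test$features)))
  sp$test <- wingsense:::subset_features(sp$test, perm)
  m2 <- fit_subspace(sp$train, sspoc_params())
  expect_identical(m1$Psi, m2$Psi)
  expect_identical(m1$w, m2$w)
  a <- fit_and_score(sp$train, sp$test, 1:3)$accuracy
  sp$test <- wingsense:::subset_features(sp$test, order(perm))
  b <- fit_and_score(sp$train, sp$test, 1:3)$accuracy
  expect_equal(a, b)
})

test_that("replicate accuracy reports mean and dispersion over fresh runs", {
  task <- surrogate_task(c(0.1, 0.7), noise = 0.02)
  reps <- replicate_accuracy(task, n_replicates = 3, seed = 2)
  expect_equal(nrow(reps), 3L)
  gl <- glance(reps)
  expect_true(gl$mean_accuracy >= 0.5 && gl$mean_accuracy <= 1)
  expect_gte(gl$sd_accuracy, 0)
  # a deterministic, perfectly separable feature source: every replicate is
  # perfect regardless of the split, so the replicate s.d. is exactly 0
  det_fn <- function(task, seed) {
    X <- matrix(0, 200, 10)
    y <- factor(rep(c("none", "rot"), each = 100))
    X[y == "rot", 1:3] <- 7.4
    wingsense:::new_spike_features(X, n_wb = 20, n_reps = 10, dt_ms = 0.1,
                                   period_ms = 40, label = y)
  }
  dtask <- detection_task(axis = "yaw", sspoc = sspoc_params(k = 3),
                          data_fn = det_fn)
  dreps <- replicate_accuracy(dtask, n_replicates = 3, seed = 2)
  expect_equal(glance(dreps)$sd_accuracy, 0)
  expect_equal(glance(dreps)$mean_accuracy, 1)
  # the driver itself is a pure function of (task, seed)
  expect_equal(replicate_accuracy(task, n_replicates = 2, seed = 9),
               replicate_accuracy(task, n_replicates = 2, seed = 9))
  expect_error(replicate_accuracy(task, n_replicates = 1), "at least 2")
})

test_that("multi-class nearest-centroid readout handles four classes", {
  set.seed(12)
  n_per <- 100
  X <- matrix(rnorm(4 * n_per * 8, sd = 0.1), 4 * n_per, 8)
  y <- factor(rep(c("none", "yaw", "pitch", "roll"), each = n_per))
  centers <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  X[, 1:2] <- X[, 1:2] + centers[as.integer(y), ]
  fe <- wingsense:::new_spike_features(X, n_wb = 40, n_reps = 10,
                                       dt_ms = 0.1, period_ms = 40, label = y)
  sp <- split_data(fe, 0.9, seed = 1)
  sc <- fit_and_score(sp$train, sp$test, 1:8)
  expect_equal(sc$rule, "nearest_centroid")
  expect_gt(sc$accuracy, 0.95)
  expect_equal(dim(sc$confusion), c(4L, 4L))
})
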