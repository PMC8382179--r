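# Plate model and strain-field generator.

test_that("candidate grid has the full lattice with documented ordering", {
  g <- sensor_grid()
  co <- grid_coordinates(g)
  expect_equal(g$n_locations, 1326L)
  expect_equal(nrow(co), 1326L)
  expect_equal(length(unique(co$span_mm)), 51L)
  expect_equal(length(unique(co$chord_mm)), 26L)
  # spanwise-major ordering: first location is the base leading-edge corner,
  # last the tip trailing-edge corner
  expect_equal(unlist(co[1, c("span_mm", "chord_mm")]), c(span_mm = 0, chord_mm = 0))
  expect_equal(unlist(co[1326, c("span_mm", "chord_mm")]), c(span_mm = 50, chord_mm = 25))
  expect_equal(grid_corners(g), c(1L, 26L, 1301L, 1326L))
  # region masks partition the planform
  expect_length(union(grid_region(g, "proximal"), grid_region(g, "distal")), 1326L)
})

test_that("zero forcing yields identically zero strain", {
  f <- simulate_strain(wing_params(),
                       flapping_kinematics(peak_amplitude = 0,
                                           flapping_noise_frac = 0),
                       rotation_condition("none"), duration = 0.2, seed = 1)
  expect_equal(strain_peak(f), 0)
})

test_that("simulation is deterministic given the seed", {
  f1 <- simulate_strain(duration = 0.2, seed = 42)
  f2 <- simulate_strain(duration = 0.2, seed = 42)
  f3 <- simulate_strain(duration = 0.2, seed = 43)
  expect_identical(f1$q, f2$q)
  expect_false(identical(f1$q, f3$q))
})

test_that("noise-free flapping strain is periodic at the wingbeat", {
  # lightly damped start-up transient decays over ~1 s; compare steady beats
  f <- quiet_sim(duration = 1.6)
  x <- strain_matrix(f, c(40, 400, 900, 1326))
  w <- round(0.04 / f$dt)
  b1 <- as.vector(x[(35 * w + 1):(36 * w), ])
  b2 <- as.vector(x[(36 * w + 1):(37 * w), ])
  expect_gt(cor(b1, b2), 0.999)
})

test_that("strain amplitude falls with stiffness across the studied range", {
  sfs <- c(0.25, 0.5, 1, 2, 3.33)
  pks <- vapply(sfs, function(sf)
    strain_peak(quiet_sim(stiffness_factor = sf, duration = 0.2)), 1)
  # overall decreasing trend; resonance crossings of the flapping harmonics
  # superimpose local peaks, so the assertion is on the trend and on the
  # off-resonance comparisons, not on pointwise monotonicity
  expect_lt(cor(log(sfs), log(pks), method = "spearman"), -0.5)
  expect_gt(pks[1], pks[5])
  expect_gt(pks[3], pks[4])  # 3 GPa vs 6 GPa (quasi-static 1/E oracle)
  expect_gt(pks[4], pks[5])
})

test_that("yaw excites corner-concentrated, chord-antisymmetric strain", {
  f0 <- quiet_sim("none", duration = 1)
  fy <- quiet_sim("yaw", duration = 1)
  fr <- quiet_sim("roll", duration = 1)
  d <- colMeans(abs(strain_matrix(fy) - strain_matrix(f0)))
  co <- grid_coordinates()
  am <- which.max(d)
  # the largest differences concentrate in a corner quadrant: on a chordwise
  # edge row, in the outer (or inner) quarter of the span
  expect_true(co$chord_frac[am] %in% c(0, 1))
  expect_true(co$span_frac[am] >= 0.75 || co$span_frac[am] <= 0.25)
  # twist-mode projection: yaw >> roll at matched rate
  co <- grid_coordinates()
  wtw <- co$span_frac * (2 * co$chord_frac - 1)
  wtw <- wtw / sqrt(sum(wtw^2))
  twist <- function(f) mean(abs((strain_matrix(f) - strain_matrix(f0)) %*% wtw))
  expect_gt(twist(fy), 10 * twist(fr))
})

test_that("integration stays convergent over the full stiffness range", {
  for (sf in c(0.7 / 3, 10 / 3)) {
    f <- quiet_sim(stiffness_factor = sf, duration = 0.2)
    expect_true(all(is.finite(f$q)))
  }
})

test_that("modal basis is converged: doubling changes peak strain < 2%", {
  p1 <- strain_peak(quiet_sim(duration = 0.2))
  p2 <- strain_peak(quiet_sim(duration = 0.2, n_span = 6, n_chord = 4))
  expect_lt(abs(p2 - p1) / p1, 0.02)
})

test_that("parameter validation enforces the studied ranges", {
  expect_error(wing_params(stiffness_factor = 0.1), class = "wingsense_convergence_error")
  expect_error(simulate_strain(duration = 0.03), "multiple of the wingbeat")
  expect_error(rotation_condition("none", disturbance_sd_frac = 0.5),
               "disturbance_axis")
})

test_that("surrogate fields are deterministic and class-controlled", {
  g <- small_grid()
  s1 <- surrogate_strain(g, list(twist_amp = 0.3), seed = 9, duration = 0.2)
  s2 <- surrogate_strain(g, list(twist_amp = 0.3), seed = 9, duration = 0.2)
  expect_identical(s1$q, s2$q)
  # zero twist for both classes leaves the fields class-indistinguishable
  a <- surrogate_strain(g, list(twist_amp = 0, noise = 0), seed = 1, duration = 0.2)
  b <- surrogate_strain(g, list(twist_amp = 0, noise = 0), seed = 2, duration = 0.2)
  expect_equal(strain_matrix(a), strain_matrix(b))
})

test_that("strain fields tidy into long location-annotated tibbles", {
  f <- quiet_sim(duration = 0.2)
  tb <- tidy(f, locations = c(1, 1326))
  expect_s3_class(tb, "tbl_df")
  expect_equal(nrow(tb), 2 * f$n_time)
  expect_equal(unique(tb$span_mm), c(0, 50))
})
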