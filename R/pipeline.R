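# End-to-end detection pipeline: simulate condition pair(s), encode, select
# sensors, evaluate. A detection_task bundles every parameter; run_detection
# executes one replicate from one seed.

.norm_cache <- new.env(parent = emptyenv())

#' Reference normalization constant (cached)
#'
#' Simulates the noise-free flapping-only reference condition at stiffness
#' factor 1 and returns the constant that scales its maximum filtered strain
#' to exactly 1. Cached per (kinematics, filter, duration, direction, basis)
#' so sweeps reuse one constant across all stiffnesses and conditions.
#'
#' @param kin A [flapping_kinematics()] (noise is ignored for the reference).
#' @param enc An [encoder_params()].
#' @param duration,direction,dt,grid,n_span,n_chord Simulation settings, as
#'   in [simulate_strain()].
#' @return Scalar normalization constant.
#' @export
reference_norm_constant <- function(kin = flapping_kinematics(),
                                    enc = encoder_params(),
                                    duration = 3,
                                    direction = "spanwise", dt = 1e-4,
                                    grid = sensor_grid(),
                                    n_span = 4, n_chord = 3) {
  key <- paste(kin$primary_freq, kin$secondary_freq, kin$secondary_rel_amplitude,
               kin$peak_amplitude, enc$omega, enc$omega_scale, enc$tau,
               enc$delta, duration, direction, dt,
               grid$spanwise_count, grid$chordwise_count, n_span, n_chord,
               sep = "|")
  if (!is.null(.norm_cache[[key]])) return(.norm_cache[[key]])
  kin0 <- kin; kin0$flapping_noise_frac <- 0
  ref <- simulate_strain(wing_params(stiffness_factor = 1), kin0,
                         rotation_condition("none"), duration = duration,
                         seed = 1, direction = direction, grid = grid,
                         dt = dt, n_span = n_span, n_chord = n_chord)
  nc <- compute_norm_constant(ref, enc)
  .norm_cache[[key]] <- nc
  nc
}

#' Define a rotation-detection task
#'
#' Bundles all parameters of one classification task: which rotation
#' condition(s) to discriminate from flapping-only, at which wing stiffness
#' and neural threshold, with which SSPOC settings.
#'
#' @param axis Rotation axis to detect (`"yaw"`, `"pitch"`, `"roll"`), or a
#'   character vector of several axes for multi-way classification (the
#'   flapping-only class is always included).
#' @param wing A [wing_params()].
#' @param kin A [flapping_kinematics()].
#' @param enc An [encoder_params()]; `norm_constant` is filled from the
#'   reference simulation if unset.
#' @param sspoc An [sspoc_params()].
#' @param rate Rotation rate, rad/s.
#' @param duration Simulated time per condition, seconds (a multiple of the
#'   40 ms wingbeat).
#' @param n_repeats Spike-train realizations per simulation.
#' @param train_frac Training fraction for the 90/10 split.
#' @param direction Strain component used by the sensors.
#' @param mask Optional candidate-location mask (e.g. [grid_region()]).
#' @param disturbance_sd_frac Rotation-rate disturbance (fraction of `rate`)
#'   applied to both classes of the evaluation data.
#' @param noise Logical; include the flapping/rotation process noises.
#' @param grid,dt,n_span,n_chord Simulation settings.
#' @param data_fn Optional override: `function(task, seed)` returning a
#'   labelled `spike_features` (used to run the pipeline on surrogate data).
#' @return A `detection_task` object.
#' @export
detection_task <- function(axis = "yaw", wing = wing_params(),
                           kin = flapping_kinematics(), enc = encoder_params(),
                           sspoc = sspoc_params(), rate = 10, duration = 3,
                           n_repeats = 10, train_frac = 0.9,
                           direction = "spanwise", mask = NULL,
                           disturbance_sd_frac = 0, noise = TRUE,
                           grid = sensor_grid(), dt = 1e-4,
                           n_span = 4, n_chord = 3, data_fn = NULL) {
  stopifnot(all(axis %in% c("yaw", "pitch", "roll")))
  structure(
    list(axis = axis, wing = wing, kin = kin, enc = enc, sspoc = sspoc,
         rate = rate, duration = duration, n_repeats = n_repeats,
         train_frac = train_frac, direction = direction, mask = mask,
         disturbance_sd_frac = disturbance_sd_frac, noise = isTRUE(noise),
         grid = grid, dt = dt, n_span = n_span, n_chord = n_chord,
         data_fn = data_fn,
         multiclass = length(axis) > 1),
    class = "detection_task")
}

# Rotation condition for one class of a task. The flapping-only class still
# carries the disturbance (about the task axis) and, for multi-way tasks,
# rotation noise about all axes.
task_condition <- function(task, axis) {
  all_axes <- task$multiclass
  if (axis == "none") {
    rotation_condition("none",
                       rotation_noise_frac = 0,
                       disturbance_sd_frac = task$disturbance_sd_frac,
                       disturbance_axis = if (task$disturbance_sd_frac > 0) task$axis[1] else NULL,
                       noise_all_axes = all_axes && task$noise)
  } else {
    rotation_condition(axis, rate = task$rate,
                       rotation_noise_frac = if (!task$noise) 0 else NULL,
                       disturbance_sd_frac = task$disturbance_sd_frac,
                       noise_all_axes = all_axes && task$noise)
  }
}

# Labelled first-spike features for all classes of a task, fresh simulation
# and spiking noise from one seed.
task_features <- function(task, seed) {
  if (!is.null(task$data_fn)) return(task$data_fn(task, seed))
  kin <- task$kin
  if (!task$noise) kin$flapping_noise_frac <- 0
  enc <- task$enc
  if (is.na(enc$norm_constant)) {
    enc$norm_constant <- reference_norm_constant(
      task$kin, enc, duration = task$duration, direction = task$direction,
      dt = task$dt, grid = task$grid, n_span = task$n_span,
      n_chord = task$n_chord)
  }
  labels <- c("none", task$axis)
  seeds <- derive_seeds(seed, 2 * length(labels))
  feats <- purrr::imap(labels, function(ax, i) {
    fld <- simulate_strain(task$wing, kin, task_condition(task, ax),
                           duration = task$duration, seed = seeds[2 * i - 1],
                           direction = task$direction, grid = task$grid,
                           dt = task$dt, n_span = task$n_span,
                           n_chord = task$n_chord)
    encode_strain(fld, enc, n_repeats = task$n_repeats, seed = seeds[2 * i])
  })
  bind_features(feats, labels)
}

#' Run one replicate of a detection task
#'
#' Simulate (or draw via `data_fn`), encode, split 90/10, fit the SSPOC
#' subspace and sparse weights on the training split, keep the top-k
#' sensors, and score the centroid readout on the held-out split.
#'
#' @param task A [detection_task()].
#' @param seed Integer seed for this replicate.
#' @param features Optional precomputed labelled `spike_features` (skips
#'   simulation).
#' @return A `detection_fit`: accuracy score, selected sensors, weights,
#'   subspace model, the split, and the mean spanwise fraction of the
#'   selected sensors.
#' @export
run_detection <- function(task, seed = 1, features = NULL) {
  if (is.null(features)) features <- task_features(task, seed)
  sp <- split_data(features, train_frac = task$train_frac,
                   seed = seed + 1L)
  model <- fit_subspace(sp$train, task$sspoc, mask = task$mask)
  weights <- if (length(model$classes) > 2) {
    solve_sensors_multiclass(model, task$sspoc)
  } else {
    solve_sensors_2class(model, task$sspoc)
  }
  sel <- weights$selected
  score <- fit_and_score(sp$train, sp$test, sel)
  co <- grid_coordinates(task$grid)
  structure(
    list(task = task, seed = seed, score = score, selected = sel,
         weights = weights, model = model, split = sp,
         mean_span_frac = mean(co$span_frac[sel]),
         mean_chord_frac = mean(co$chord_frac[sel])),
    class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("<detection_fit> %s: %.1f%% accuracy, top-%d sensors at mean span fraction %.2f\n",
              paste(x$task$axis, collapse = "+"), 100 * x$score$accuracy,
              length(x$selected), x$mean_span_frac))
  invisible(x)
}

#' @export
glance.detection_fit <- function(x, ...) {
  tibble::tibble(accuracy = x$score$accuracy, n_test = x$score$n_test,
                 mean_span_frac = x$mean_span_frac,
                 residual = max(x$weights$residual, 0))
}

#' @export
tidy.detection_fit <- function(x, ...) {
  co <- grid_coordinates(x$task$grid)
  co[x$selected, ] |>
    dplyr::mutate(rank = dplyr::row_number(),
                  weight = x$weights$aggregate[x$selected])
}
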