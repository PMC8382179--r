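# Figure-level experiment drivers: stiffness x threshold sweeps, optimal
# location maps, sensor dropout, disturbance robustness, four-way
# classification. All are pure functions of (spec, seed).

#' Stiffness-by-threshold accuracy sweep
#'
#' For every (stiffness factor, neural threshold) cell: simulate the
#' condition pair, encode, select the top-k sensors by SSPOC, and score the
#' held-out readout, over independent replicate data sets. Strain fields are
#' simulated once per (stiffness, replicate) and reused across thresholds.
#'
#' @param task A [detection_task()] providing every non-swept parameter.
#' @param stiffness_factors Numeric grid of stiffness factors (1 = 3 GPa).
#' @param betas Numeric grid of neural thresholds.
#' @param n_replicates Replicate data sets per cell.
#' @param seed Integer seed.
#' @return An `accuracy_map` tibble: one row per (cell, replicate) with
#'   accuracy, mean spanwise fraction of selected sensors, and the selected
#'   locations as a list column. Summarize with [summarize_map()].
#' @export
run_sweep <- function(task, stiffness_factors = c(0.25, 0.4, 0.65, 1, 1.6, 2.2, 3.3),
                      betas = seq(0.05, 0.7, length.out = 8),
                      n_replicates = 10, seed = 1) {
  stopifnot(length(stiffness_factors) >= 1, length(betas) >= 1)
  enc0 <- task$enc
  if (is.na(enc0$norm_constant)) {
    enc0$norm_constant <- reference_norm_constant(
      task$kin, enc0, duration = task$duration, direction = task$direction,
      dt = task$dt, grid = task$grid, n_span = task$n_span, n_chord = task$n_chord)
  }
  kin <- task$kin
  if (!task$noise) kin$flapping_noise_frac <- 0
  labels <- c("none", task$axis)
  rep_seeds <- derive_seeds(seed, n_replicates)

  rows <- list()
  for (r in seq_len(n_replicates)) {
    seeds <- derive_seeds(rep_seeds[r], 2 * length(labels) * length(stiffness_factors))
    si <- 0
    for (sf in stiffness_factors) {
      wing <- task$wing
      wing <- wing_params(stiffness_factor = sf, span = wing$span,
                          chord = wing$chord, thickness = wing$thickness,
                          material_density = wing$material_density,
                          poisson_ratio = wing$poisson_ratio,
                          damping_ratio = wing$damping_ratio)
      gmats <- tryCatch(
        purrr::map(labels, function(ax) {
          si <<- si + 1
          fld <- simulate_strain(wing, kin, task_condition(task, ax),
                                 duration = task$duration, seed = seeds[si],
                                 direction = task$direction, grid = task$grid,
                                 dt = task$dt, n_span = task$n_span,
                                 n_chord = task$n_chord)
          # filtered, normalized g reused across all thresholds
          strain_matrix(filter_strain(fld, enc0))
        }),
        wingsense_convergence_error = function(e) {
          warn(conditionMessage(e))
          NULL
        })
      for (beta in betas) {
        if (is.null(gmats)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            stiffness_factor = sf, beta = beta, replicate = r,
            accuracy = NA_real_, n_test = NA_integer_,
            mean_span_frac = NA_real_, selected = list(integer()),
            valid = FALSE)
          next
        }
        enc <- enc0; enc$beta <- beta
        feats <- purrr::imap(gmats, function(G, i) {
          si_enc <- seeds[si] + 7L * i + round(1e4 * beta)
          encode_g(G, enc, n_repeats = task$n_repeats, seed = si_enc,
                   dt_ms = task$dt * 1e3, period_ms = 1e3 / kin$primary_freq)
        })
        fit <- run_detection(task, seed = rep_seeds[r] + round(1e4 * beta),
                             features = bind_features(feats, labels))
        rows[[length(rows) + 1]] <- tibble::tibble(
          stiffness_factor = sf, beta = beta, replicate = r,
          accuracy = fit$score$accuracy, n_test = fit$score$n_test,
          mean_span_frac = fit$mean_span_frac,
          selected = list(fit$selected), valid = TRUE)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accuracy_map", class(out))
  attr(out, "task") <- task
  attr(out, "seed") <- seed
  out
}

#' Summarize an accuracy map over replicates
#'
#' @param map An `accuracy_map` from [run_sweep()].
#' @return Tibble with one row per (stiffness_factor, beta): mean and s.d.
#'   accuracy, mean spanwise fraction of selected sensors, replicate count.
#' @export
summarize_map <- function(map) {
  map |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$stiffness_factor, .data$beta) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      mean_span_frac = mean(.data$mean_span_frac),
      n_replicates = dplyr::n(),
      .groups = "drop")
}

#' Spanwise-location summary with accuracy cutoffs
#'
#' For each parameter cell, the mean spanwise coordinate (fraction of span,
#' 0 = base, 1 = tip) of the selected sensors, masked (NA) where mean
#' accuracy falls below each cutoff.
#'
#' @param map An `accuracy_map`.
#' @param accuracy_cutoffs Numeric vector of accuracy cutoffs in (0, 1].
#' @return Tibble with columns `cutoff`, `stiffness_factor`, `beta`,
#'   `mean_span_frac` (NA below cutoff), `masked`.
#' @export
spanwise_summary <- function(map, accuracy_cutoffs = c(0.5, 0.75, 0.95)) {
  sm <- summarize_map(map)
  purrr::map_dfr(accuracy_cutoffs, function(cut) {
    dplyr::mutate(sm,
                  cutoff = cut,
                  masked = .data$mean_accuracy < cut,
                  mean_span_frac = ifelse(.data$masked, NA_real_, .data$mean_span_frac)) |>
      dplyr::select("cutoff", "stiffness_factor", "beta", "mean_accuracy",
                    "mean_span_frac", "masked")
  })
}

#' Sensor-dropout robustness
#'
#' Starting from the fitted top-10 solution, randomly retains `n_keep`
#' sensors, refits the LDA readout on the training split restricted to the
#' kept sensors, and scores held-out accuracy, averaged over random draws
#' and replicates.
#'
#' @param task A [detection_task()].
#' @param n_keep Integer grid of sensors retained (default 1..k).
#' @param n_draws Random subsets per `n_keep` (a single draw is used when
#'   `n_keep` equals the full set).
#' @param n_replicates Replicate data sets.
#' @param seed Integer seed.
#' @return A `dropout_result` tibble: one row per (replicate, n_keep, draw).
#' @export
dropout_analysis <- function(task, n_keep = NULL, n_draws = 20,
                             n_replicates = 5, seed = 1) {
  k <- task$sspoc$k
  if (is.null(n_keep)) n_keep <- seq_len(k)
  if (any(n_keep < 1)) abort("n_keep must be at least 1 (no sensors left otherwise)")
  rep_seeds <- derive_seeds(seed, n_replicates)
  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    fit <- run_detection(task, seed = rep_seeds[r])
    draw_seeds <- derive_seeds(rep_seeds[r] + 1L, length(n_keep))
    purrr::map_dfr(seq_along(n_keep), function(ki) {
      nk <- n_keep[ki]
      nd <- if (nk >= length(fit$selected)) 1L else n_draws
      subsets <- with_seed(draw_seeds[ki], {
        lapply(seq_len(nd), function(d) sort(sample(fit$selected, nk)))
      })
      purrr::imap_dfr(subsets, function(keep, d) {
        sc <- fit_and_score(fit$split$train, fit$split$test, keep)
        tibble::tibble(replicate = r, n_keep = nk, draw = d,
                       accuracy = sc$accuracy,
                       base_accuracy = fit$score$accuracy)
      })
    })
  })
  class(rows) <- c("dropout_result", class(rows))
  rows
}

#' External-disturbance robustness
#'
#' Sensors are selected and the readout fitted at zero disturbance; accuracy
#' is then re-evaluated on freshly simulated data in which a slowly varying
#' random rotation-rate perturbation (s.d. expressed as a fraction of the
#' nominal rate) is applied to both classes. The readout is refit on the
#' disturbed training split over the fixed sensor locations.
#'
#' @param task A [detection_task()] (its own `disturbance_sd_frac` is
#'   ignored).
#' @param sd_fracs Disturbance grid, fractions of the nominal rate (0 reuses
#'   the undisturbed data set).
#' @param n_replicates Replicate data sets.
#' @param seed Integer seed.
#' @return A `disturbance_result` tibble: one row per (replicate, sd_frac).
#' @export
disturbance_analysis <- function(task, sd_fracs = c(0, 0.25, 0.5, 1),
                                 n_replicates = 5, seed = 1) {
  stopifnot(all(sd_fracs >= 0))
  rep_seeds <- derive_seeds(seed, n_replicates)
  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    base_task <- task; base_task$disturbance_sd_frac <- 0
    fit <- run_detection(base_task, seed = rep_seeds[r])
    purrr::map_dfr(sd_fracs, function(sdf) {
      if (sdf == 0) {
        acc <- fit$score$accuracy
      } else {
        dtask <- task; dtask$disturbance_sd_frac <- sdf
        feats <- task_features(dtask, seed = rep_seeds[r] + 31L + round(1e3 * sdf))
        sp <- split_data(feats, train_frac = task$train_frac,
                         seed = rep_seeds[r] + 1L)
        acc <- fit_and_score(sp$train, sp$test, fit$selected)$accuracy
      }
      tibble::tibble(replicate = r, sd_frac = sdf, accuracy = acc,
                     base_accuracy = fit$score$accuracy)
    })
  })
  class(rows) <- c("disturbance_result", class(rows))
  rows
}

#' Four-way rotation classification
#'
#' Classifies flapping-only vs yaw vs pitch vs roll in one task, using the
#' relaxed multi-class sparse recovery and the nearest-centroid rule.
#' Rotation-rate noise about all three axes is included in every condition.
#'
#' @param task A [detection_task()] whose `axis` lists the rotation classes
#'   (default all three).
#' @param n_replicates Replicate data sets.
#' @param seed Integer seed.
#' @return A `fourway_result` tibble with per-replicate accuracy and the
#'   pooled confusion matrix in attribute `confusion`.
#' @export
four_way_experiment <- function(task = NULL, n_replicates = 5, seed = 1) {
  if (is.null(task)) task <- detection_task(axis = c("yaw", "pitch", "roll"))
  if (!task$multiclass) abort("task must list at least two rotation axes")
  rep_seeds <- derive_seeds(seed, n_replicates)
  conf <- NULL
  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    fit <- run_detection(task, seed = rep_seeds[r])
    cm <- fit$score$confusion
    conf <<- if (is.null(conf)) cm else conf + cm
    tibble::tibble(replicate = r, accuracy = fit$score$accuracy,
                   n_test = fit$score$n_test,
                   mean_span_frac = fit$mean_span_frac)
  })
  class(rows) <- c("fourway_result", class(rows))
  attr(rows, "confusion") <- conf
  rows
}

#' Calibrated high-performing parameter combinations
#'
#' Two (stiffness factor, threshold) combinations per axis that land in the
#' near-peak accuracy regimes of the stiffness-by-threshold sweeps: for yaw,
#' one yielding wing-tip sensors and one wing-base; for pitch and roll both
#' lie in the wing-base regime. Calibrated once from package sweeps (see the
#' methods vignette) and used by the robustness analyses.
#'
#' @param axis `"yaw"`, `"pitch"` or `"roll"`.
#' @return Tibble with columns `stiffness_factor`, `beta`, `regime`.
#' @export
highlight_params <- function(axis = c("yaw", "pitch", "roll")) {
  axis <- match.arg(axis)
  switch(axis,
    yaw = tibble::tibble(stiffness_factor = c(1, 1),
                         beta = c(0.14, 0.33),
                         regime = c("tip", "base")),
    pitch = tibble::tibble(stiffness_factor = c(1, 1),
                           beta = c(0.14, 0.24),
                           regime = c("base", "base")),
    roll = tibble::tibble(stiffness_factor = c(1, 1),
                          beta = c(0.14, 0.24),
                          regime = c("base", "base")))
}
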