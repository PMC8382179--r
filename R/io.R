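# Configuration round-tripping, result persistence, and deterministic
# fixtures for the test suite.

.config_defaults <- function() {
  list(
    wing = list(stiffness_factor = 1, span = 50e-3, chord = 25e-3,
                thickness = 0.127e-3, material_density = 1200,
                poisson_ratio = 0.3, damping_ratio = 0.02),
    kinematics = list(primary_freq = 25, secondary_freq = 50,
                      secondary_rel_amplitude = 0.76, peak_amplitude = 0.01,
                      flapping_noise_frac = 0.02),
    rotation = list(axis = "yaw", rate = 10, rotation_noise_frac = 0.01,
                    disturbance_sd_frac = 0),
    encoder = list(omega = 1 / (2 * pi), omega_scale = 1, tau = 5, delta = 4,
                   alpha = 50, beta = 0.2, refractory = 15),
    sspoc = list(m = 3, lam = 0.9, eps = 1e-6, k = 10),
    run = list(duration = 3, dt = 1e-4, n_repeats = 10, train_frac = 0.9,
               direction = "spanwise", seed = 1))
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills every missing field with the
#' package defaults (25 Hz flapping, 10 rad/s rotation, beta = 0.2,
#' lambda = 0.9, m = 3, k = 10, 15 ms refractory, ...), validates ranges via
#' the parameter constructors, and rejects unknown keys by name.
#'
#' @param path File path, or `NULL` for pure defaults.
#' @param allow_beta_outside Allow thresholds outside the studied
#'   0.05--0.7 range.
#' @return A validated `run_config` (nested named list).
#' @export
load_config <- function(path = NULL, allow_beta_outside = FALSE) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    for (sec in names(user)) {
      if (!sec %in% names(cfg)) {
        abort(sprintf("unknown configuration section '%s'", sec))
      }
      for (key in names(user[[sec]])) {
        if (!key %in% names(cfg[[sec]])) {
          abort(sprintf("unknown configuration key '%s$%s'", sec, key))
        }
        cfg[[sec]][[key]] <- user[[sec]][[key]]
      }
    }
  }
  validate_config(cfg, allow_beta_outside = allow_beta_outside)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg, allow_beta_outside = FALSE) {
  do.call(wing_params, cfg$wing[setdiff(names(cfg$wing), "stiffness_factor")] |>
            c(list(stiffness_factor = cfg$wing$stiffness_factor)))
  do.call(flapping_kinematics, cfg$kinematics)
  rot <- cfg$rotation
  rotation_condition(rot$axis, rate = rot$rate,
                     rotation_noise_frac = rot$rotation_noise_frac,
                     disturbance_sd_frac = rot$disturbance_sd_frac)
  beta <- cfg$encoder$beta
  if (!allow_beta_outside && (beta < 0.05 || beta > 0.7)) {
    abort(sprintf("encoder$beta = %g is outside the studied range [0.05, 0.7]", beta))
  }
  do.call(encoder_params, cfg$encoder)
  do.call(sspoc_params, cfg$sspoc)
  with(cfg$run, stopifnot(duration > 0, dt > 0, n_repeats >= 1,
                          train_frac > 0, train_frac < 1,
                          direction %in% c("spanwise", "chordwise")))
  invisible(cfg)
}

#' Save a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Build a [detection_task()] from a configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A `detection_task`.
#' @export
config_task <- function(cfg) {
  detection_task(
    axis = cfg$rotation$axis,
    wing = do.call(wing_params, cfg$wing),
    kin = do.call(flapping_kinematics, cfg$kinematics),
    enc = do.call(encoder_params, cfg$encoder),
    sspoc = do.call(sspoc_params, cfg$sspoc),
    rate = cfg$rotation$rate,
    duration = cfg$run$duration,
    n_repeats = cfg$run$n_repeats,
    train_frac = cfg$run$train_frac,
    direction = cfg$run$direction,
    disturbance_sd_frac = cfg$rotation$disturbance_sd_frac,
    dt = cfg$run$dt)
}

#' Write first-spike features to CSV
#'
#' Observations by sensors, with observation metadata (wingbeat, repeat,
#' label) in leading columns; round-trips through [read_features_csv()].
#'
#' @param sf A `spike_features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(sf, path) {
  readr::write_csv(tidy(sf), path)
  invisible(path)
}

#' Read first-spike features from CSV
#'
#' @param path A file written by [write_features_csv()].
#' @param period_ms Wingbeat period, ms.
#' @return A `spike_features`.
#' @export
read_features_csv <- function(path, period_ms = 40) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  loc_cols <- grep("^loc", names(tb), value = TRUE)
  feats <- as.matrix(tb[, loc_cols])
  dimnames(feats) <- NULL
  out <- new_spike_features(feats,
                            n_wb = max(tb$wingbeat), n_reps = max(tb$rep),
                            dt_ms = 0.1, period_ms = period_ms,
                            label = if ("label" %in% names(tb)) factor(tb$label))
  out$wingbeat <- tb$wingbeat
  out$rep <- tb$rep
  out
}

#' Deterministic surrogate fixtures for testing the decision pipeline
#'
#' Small labelled data sets built on [surrogate_strain()]: `"separable"`
#' (large twist-amplitude difference between classes, negligible noise, so
#' downstream accuracy is 1) and `"chance"` (identical class parameters, so
#' accuracy is at chance).
#'
#' @param kind `"separable"` or `"chance"`.
#' @param seed Integer seed.
#' @param grid A [sensor_grid()] (defaults to a reduced 11 x 6 lattice).
#' @param duration Seconds of surrogate data per class.
#' @param n_repeats Spike repeats per class.
#' @return A labelled `spike_features`.
#' @export
make_fixtures <- function(kind = c("separable", "chance"), seed = 1,
                          grid = sensor_grid(11, 6), duration = 0.6,
                          n_repeats = 5) {
  kind <- match.arg(kind)
  amps <- if (kind == "separable") c(0.05, 0.9) else c(0.3, 0.3)
  noise <- if (kind == "separable") 0.01 else 0.05
  enc <- encoder_params(beta = 0.4, norm_constant = NA)
  seeds <- derive_seeds(seed, 4)
  fields <- purrr::map2(amps, seeds[1:2], function(a, s) {
    surrogate_strain(grid, list(twist_amp = a, noise = noise), seed = s,
                     duration = duration)
  })
  enc$norm_constant <- compute_norm_constant(fields[[1]], enc)
  feats <- purrr::map2(fields, seeds[3:4], function(f, s) {
    encode_strain(f, enc, n_repeats = n_repeats, seed = s)
  })
  bind_features(feats, c("none", "rotation"))
}
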