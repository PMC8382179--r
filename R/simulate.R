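# Strain-field simulation: prescribed flapping + body rotation drive the
# modal plate equations in the rotating wing frame. Transverse forcing per
# unit area is -rho h * (Euler + centrifugal) acceleration:
#   f_z = rho h [ wdot_y x - wdot_x y - w_z w_x x - w_z w_y y + (w_x^2 + w_y^2) w ]
# plus spanwise membrane tension from in-plane centrifugal loading
# (rotating-cantilever stiffening, entering as w_y^2 G). The transverse
# Coriolis component vanishes for a flat plate with out-of-plane motion only.

# Evaluate with a temporary RNG state so explicit seeds do not perturb the
# caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stationary AR(1) noise with correlation time tau_s, sd `sd`, step dt_s.
ar1_noise <- function(n, sd, tau_s, dt_s) {
  if (sd <= 0) return(rep(0, n))
  phi <- exp(-dt_s / tau_s)
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  e <- rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + e[i - 1]
  x
}

# Normalization so the two-harmonic flapping waveform peaks at 1.
.flap_norm <- function(r) {
  th <- seq(0, 2 * pi, length.out = 4001)
  max(abs(sin(th) + r * sin(2 * th)))
}

# Body-rotation axes resolved in the flapping wing frame at flapping angle
# phi. Flapping rotates the wing about the chordwise (y) axis, which
# coincides with the body roll axis; yaw is the body-vertical axis and pitch
# the body-transverse (spanwise at midstroke) axis.
.axis_in_wing <- function(axis, phi) {
  switch(axis,
    yaw   = list(x = -sin(phi), y = 0 * phi, z = cos(phi)),
    pitch = list(x = cos(phi), y = 0 * phi, z = sin(phi)),
    roll  = list(x = 0 * phi, y = 0 * phi + 1, z = 0 * phi))
}

# Build wing-frame angular-velocity component series on the half-step grid,
# including flapping, rotation, their noises and the disturbance probe.
#
# Gyroscopic formulation: the superimposed body rotation enters as
# angular-velocity components Omega(t) nhat(phi) resolved in the flapping
# frame (Coriolis and centrifugal coupling), while the Euler
# (angular-acceleration) term retains the prescribed flapping acceleration
# and the rate-noise derivative along the instantaneous axis. This is the
# treatment used in the flexible-wing gyroscopic-sensing model lineage; it
# yields a stationary torsional forcing ~ Omega phidot cos(phi) y for yaw,
# a weaker sin(phi)-modulated one for pitch, and none for roll (which
# shares the flapping axis). Transporting the axis exactly with the frame
# would cancel the torsional term identically and render rotations nearly
# invisible to a flat plate.
#
# Correlation times: 1 ms for the 1%/2% process noises, one wingbeat (40 ms)
# for the disturbance (a gust-like, slowly varying rate perturbation).
build_kinematics <- function(kin, rot, duration, dt) {
  n_half <- 2 * round(duration / dt) + 1
  dth <- dt / 2
  t_h <- (seq_len(n_half) - 1) * dth
  w1 <- 2 * pi * kin$primary_freq; w2 <- 2 * pi * kin$secondary_freq
  r <- kin$secondary_rel_amplitude
  A <- kin$peak_amplitude / .flap_norm(r)
  phi <- A * (sin(w1 * t_h) + r * sin(w2 * t_h))
  dphi <- A * (w1 * cos(w1 * t_h) + r * w2 * cos(w2 * t_h))
  peak_dphi <- A * (w1 + r * w2)  # nominal flapping-velocity magnitude
  dphi <- dphi + ar1_noise(n_half, kin$flapping_noise_frac * peak_dphi, 1e-3, dth)

  fd <- function(x) {  # central differences on the half-step grid
    n <- length(x)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dth)
    d[1] <- (x[2] - x[1]) / dth; d[n] <- (x[n] - x[n - 1]) / dth
    d
  }

  # per-axis body rotation rate series
  rates <- list(yaw = NULL, pitch = NULL, roll = NULL)
  if (rot$axis != "none") {
    rates[[rot$axis]] <- rot$rate +
      ar1_noise(n_half, rot$rotation_noise_frac * rot$rate, 1e-3, dth)
  }
  if (rot$noise_all_axes) {
    rate_ref <- if (rot$rate > 0) rot$rate else 10
    for (ax in c("yaw", "pitch", "roll")) {
      if (ax == rot$axis) next
      rates[[ax]] <- ar1_noise(n_half, 0.01 * rate_ref, 1e-3, dth)
    }
  }
  if (rot$disturbance_sd_frac > 0) {
    rate_ref <- if (rot$rate > 0) rot$rate else 10
    period <- 1 / kin$primary_freq
    dist <- ar1_noise(n_half, rot$disturbance_sd_frac * rate_ref, period, dth)
    dax <- rot$disturbance_axis
    rates[[dax]] <- if (is.null(rates[[dax]])) dist else rates[[dax]] + dist
  }

  wx <- numeric(n_half); wy <- dphi; wz <- numeric(n_half)
  dwx <- numeric(n_half); dwy <- fd(dphi); dwz <- numeric(n_half)
  for (ax in names(rates)) {
    if (is.null(rates[[ax]])) next
    nh <- .axis_in_wing(ax, phi)
    wx <- wx + rates[[ax]] * nh$x
    wy <- wy + rates[[ax]] * nh$y
    wz <- wz + rates[[ax]] * nh$z
    dr <- fd(rates[[ax]])
    dwx <- dwx + dr * nh$x
    dwy <- dwy + dr * nh$y
    dwz <- dwz + dr * nh$z
  }
  list(wx = wx, wy = wy, wz = wz, dwx = dwx, dwy = dwy, dwz = dwz)
}

#' Simulate the strain field on a flapping, rotating wing
#'
#' Integrates the assumed-modes Kirchhoff plate model (clamped along the
#' wing-base edge) driven by prescribed root flapping and superimposed body
#' rotation, and returns surface normal strain at every candidate sensor
#' location. The field is stored in factored form (modal time series times
#' modal strain shapes); use [strain_matrix()] to materialize the
#' time-by-location array.
#'
#' @param wing A [wing_params()].
#' @param kin A [flapping_kinematics()].
#' @param rot A [rotation_condition()].
#' @param duration Simulation length in seconds; must be a positive multiple
#'   of the wingbeat period. Default 3 s = 75 wingbeats.
#' @param seed Integer seed; the simulation is deterministic given
#'   `(parameters, seed)`.
#' @param direction Strain component: `"spanwise"` (default) or `"chordwise"`.
#' @param grid A [sensor_grid()].
#' @param dt Time step in seconds (10 kHz sampling by default).
#' @param n_span,n_chord Modal basis size (spanwise bending x chordwise
#'   functions; defaults give 12 modes).
#' @return A `strain_field` object.
#' @export
#' @examples
#' f <- simulate_strain(duration = 0.2, seed = 1)
#' dim(strain_matrix(f))
simulate_strain <- function(wing = wing_params(), kin = flapping_kinematics(),
                            rot = rotation_condition("none"), duration = 3,
                            seed = 1, direction = c("spanwise", "chordwise"),
                            grid = sensor_grid(), dt = 1e-4,
                            n_span = 4, n_chord = 3) {
  direction <- match.arg(direction)
  period <- 1 / kin$primary_freq
  n_wb <- duration / period
  if (duration <= 0 || abs(n_wb - round(n_wb)) > 1e-8) {
    abort("duration must be a positive multiple of the wingbeat period")
  }
  n_steps <- round(duration / dt)
  model <- plate_model(wing, n_span = n_span, n_chord = n_chord)

  ks <- with_seed(seed, build_kinematics(kin, rot, duration, dt))
  fx <- model$rho_h * (ks$dwy - ks$wz * ks$wx)
  fy <- -model$rho_h * (ks$dwx + ks$wz * ks$wy)
  # Transverse spin softening -(wx^2 + wy^2) w: the centrifugal coupling that
  # makes roll (which shares the flapping axis) visible as a 2 phidot Omega
  # modulation of the effective stiffness. Membrane tension stiffening is not
  # modelled (linear Kirchhoff level); the softening is far from instability
  # at the calibrated flapping amplitude (wy_max^2 << omega_1^2).
  gy <- numeric(length(ks$wy))
  gs <- ks$wx^2 + ks$wy^2

  # substep so the fastest retained mode stays well inside RK4 stability
  om_max <- 2 * pi * max(model$freqs_hz)
  n_sub <- max(1L, ceiling(om_max * dt / 1.5))
  res <- rk4_modal_cpp(model$Minv, model$K, model$C, model$G, model$M,
                       model$Px, model$Py, fx, fy, gy, gs,
                       dt, n_steps, n_sub, q_max = 1e3)
  if (isTRUE(res$diverged)) {
    abort(sprintf(
      "plate time integration diverged at t = %.4f s for Young's modulus %.3g Pa (stiffness factor %.3g); the model did not achieve numerical convergence at this stiffness",
      res$step * dt, wing$youngs_modulus, wing$stiffness_factor),
      class = "wingsense_convergence_error")
  }

  shapes <- strain_shapes(model, wing, grid, direction)
  aug <- augment_strain_rank(res$q, shapes)
  new_strain_field(q = aug$q, S = aug$S, dt = dt, duration = duration,
                   grid = grid, direction = direction, wing = wing,
                   kin = kin, rot = rot, seed = seed,
                   modal_freqs_hz = model$freqs_hz, m_linear = aug$m_linear)
}

new_strain_field <- function(q, S, dt, duration, grid, direction,
                             wing = NULL, kin = NULL, rot = NULL, seed = NA,
                             modal_freqs_hz = NULL, m_linear = ncol(q)) {
  structure(
    list(q = q, S = S, dt = dt, duration = duration, grid = grid,
         direction = direction, wing = wing, kin = kin, rot = rot,
         seed = seed, modal_freqs_hz = modal_freqs_hz, m_linear = m_linear,
         n_time = nrow(q), n_locations = nrow(S)),
    class = "strain_field")
}

#' Materialize a strain field as a time-by-location matrix
#'
#' @param field A `strain_field`.
#' @param locations Optional integer vector of location indices (defaults to
#'   all 1,326).
#' @return Numeric matrix, `n_time` rows by `length(locations)` columns,
#'   dimensionless surface strain.
#' @export
strain_matrix <- function(field, locations = NULL) {
  S <- if (is.null(locations)) field$S else field$S[locations, , drop = FALSE]
  field$q %*% t(S)
}

#' @export
as.matrix.strain_field <- function(x, ...) strain_matrix(x)

#' Peak absolute strain over all locations and times
#'
#' Computed blockwise over locations to avoid materializing the full field.
#'
#' @param field A `strain_field`.
#' @param block Locations per block.
#' @return Scalar peak |strain|.
#' @export
strain_peak <- function(field, block = 256) {
  n <- field$n_locations
  pk <- 0
  for (st in seq(1, n, by = block)) {
    idx <- st:min(st + block - 1, n)
    pk <- max(pk, max(abs(strain_matrix(field, idx))))
  }
  pk
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d steps x %d locations (%s strain), dt = %g ms, %g s\n",
              x$n_time, x$n_locations, x$direction, x$dt * 1e3, x$duration))
  if (!is.null(x$rot)) {
    cat(sprintf("  condition: %s at %g rad/s; stiffness factor %.3g; seed %s\n",
                x$rot$axis, x$rot$rate, x$wing$stiffness_factor,
                format(x$seed)))
  }
  invisible(x)
}

#' Tidy a strain field into a long tibble
#'
#' @param x A `strain_field`.
#' @param locations Location indices to extract (defaults to all; pass a
#'   subset for large fields).
#' @param ... Unused.
#' @return Tibble with `time_s`, `location`, `span_mm`, `chord_mm`, `strain`.
#' @export
tidy.strain_field <- function(x, locations = NULL, ...) {
  if (is.null(locations)) locations <- seq_len(x$n_locations)
  co <- grid_coordinates(x$grid)[locations, ]
  sm <- strain_matrix(x, locations)
  tibble::tibble(
    time_s = rep((seq_len(x$n_time) - 1) * x$dt, times = length(locations)),
    location = rep(locations, each = x$n_time),
    span_mm = rep(co$span_mm, each = x$n_time),
    chord_mm = rep(co$chord_mm, each = x$n_time),
    strain = as.vector(sm))
}

#' Fast analytic surrogate strain field
#'
#' A two-mode stand-in for the plate simulation, used for fast, controlled
#' testing of the encoding/selection/evaluation stages: a spanwise bending
#' mode (largest strain at the wing base, uniform across the chord) plus a
#' corner-antisymmetric twist mode (largest at the tip corners), each driven
#' by 25/50 Hz waveforms. The twist amplitude is class-dependent; per-wingbeat
#' lognormal-free Gaussian amplitude jitter supplies the only stochasticity.
#'
#' @param grid A [sensor_grid()].
#' @param class_params List with elements `bend_amp` (default 1), `twist_amp`
#'   (class-dependent twist strength), `twist_phase` (class-dependent twist
#'   timing, radians), `noise` (s.d. of per-wingbeat relative amplitude
#'   jitter), optional `f1`, `f2`, `sec_rel`.
#' @param seed Integer seed.
#' @param duration,dt Time base (defaults 3 s at 10 kHz).
#' @return A `strain_field`.
#' @export
surrogate_strain <- function(grid = sensor_grid(), class_params = list(),
                             seed = 1, duration = 3, dt = 1e-4) {
  p <- modifyList(list(bend_amp = 1, twist_amp = 0.1, twist_phase = pi / 4,
                       noise = 0.02, f1 = 25, f2 = 50, sec_rel = 0.76),
                  class_params)
  stopifnot(p$noise >= 0, p$bend_amp >= 0, p$twist_amp >= 0)
  period <- 1 / p$f1
  n_wb <- duration / period
  if (duration <= 0 || abs(n_wb - round(n_wb)) > 1e-8) {
    abort("duration must be a positive multiple of the wingbeat period")
  }
  n_wb <- round(n_wb)
  n_steps <- round(duration / dt)
  tt <- (seq_len(n_steps) - 1) * dt
  wb_of_t <- pmin(floor(tt / period) + 1, n_wb)

  base_wave <- sin(2 * pi * p$f1 * tt) + p$sec_rel * sin(2 * pi * p$f2 * tt)
  # two-harmonic twist waveform (class-dependent timing via twist_phase)
  twist_wave <- sin(2 * pi * p$f1 * tt + p$twist_phase) +
    p$sec_rel * sin(2 * pi * p$f2 * tt + 2 * p$twist_phase)
  jit <- with_seed(seed, list(b = rnorm(n_wb, 0, p$noise), t = rnorm(n_wb, 0, p$noise)))
  q <- cbind(p$bend_amp * (1 + jit$b[wb_of_t]) * base_wave,
             p$twist_amp * (1 + jit$t[wb_of_t]) * twist_wave)

  co <- grid_coordinates(grid)
  S <- cbind((1 + cos(pi * co$span_frac)) / 2,          # bending: max at base
             co$span_frac * (2 * co$chord_frac - 1))    # twist: max at tip corners
  kin <- flapping_kinematics(primary_freq = p$f1, secondary_freq = p$f2,
                             secondary_rel_amplitude = min(p$sec_rel, 1),
                             flapping_noise_frac = 0)
  new_strain_field(q = q, S = S, dt = dt, duration = duration, grid = grid,
                   direction = "spanwise", kin = kin, seed = seed)
}
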