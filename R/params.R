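#' Wing geometry and material parameters
#'
#' The wing is a flat rectangular plate inspired by a hawkmoth forewing:
#' 50 mm span, 25 mm chord, 0.127 mm thickness. Flexural stiffness is varied
#' through the Young's modulus; `stiffness_factor` expresses the modulus
#' relative to the 3 GPa reference, so `stiffness_factor = 1` corresponds to
#' the experimentally measured hawkmoth value. Density and Poisson ratio set
#' only the absolute strain scale (absorbed downstream by the encoder
#' normalization) and the bending/twisting coupling, respectively.
#'
#' @param stiffness_factor Young's modulus relative to 3 GPa. Validated range
#'   corresponds to 0.7--10 GPa; below 0.7 GPa the plate model does not reach
#'   numerical convergence.
#' @param youngs_modulus Young's modulus in Pa. Overrides `stiffness_factor`
#'   when given.
#' @param span,chord,thickness Plate dimensions in metres.
#' @param material_density Density in kg/m^3.
#' @param poisson_ratio Dimensionless Poisson ratio.
#' @param damping_ratio Modal damping ratio applied to every retained mode.
#'   The default 0.02 is light structural damping, which preserves the
#'   resonant sensitivity of the strain response to rotation-induced
#'   forcing.
#' @return An object of class `wing_params`.
#' @export
#' @examples
#' wing_params()                      # reference wing, 3 GPa
#' wing_params(stiffness_factor = 2)  # 6 GPa wing
wing_params <- function(stiffness_factor = 1, youngs_modulus = NULL,
                        span = 50e-3, chord = 25e-3, thickness = 0.127e-3,
                        material_density = 1200, poisson_ratio = 0.3,
                        damping_ratio = 0.02) {
  if (is.null(youngs_modulus)) youngs_modulus <- stiffness_factor * 3e9
  stiffness_factor <- youngs_modulus / 3e9
  stopifnot(span > 0, chord > 0, thickness > 0, material_density > 0,
            poisson_ratio >= 0, poisson_ratio < 0.5, damping_ratio >= 0)
  if (youngs_modulus < 0.7e9 - 1e-6) {
    abort(sprintf(
      "youngs_modulus = %.3g Pa is below the 0.7 GPa convergence limit of the plate model",
      youngs_modulus), class = "wingsense_convergence_error")
  }
  structure(
    list(span = span, chord = chord, thickness = thickness,
         youngs_modulus = youngs_modulus, stiffness_factor = stiffness_factor,
         material_density = material_density, poisson_ratio = poisson_ratio,
         damping_ratio = damping_ratio),
    class = "wing_params")
}

#' Flapping kinematics
#'
#' Wing flapping is a sum of two sinusoids: a primary component at 25 Hz and
#' a secondary at 50 Hz with 76% relative amplitude. The flapping angle is
#' scaled so its peak magnitude equals `peak_amplitude`. Multiplicative
#' white noise (2% of the peak flapping angular velocity by default) is added
#' to the flapping rate during simulation.
#'
#' @param primary_freq Primary flapping frequency, Hz.
#' @param secondary_freq Secondary frequency, Hz.
#' @param secondary_rel_amplitude Secondary amplitude relative to primary.
#' @param peak_amplitude Peak flapping angle, radians. The default is
#'   calibrated so the reference wing's peak tip deflection is about two
#'   plate thicknesses -- the weakly nonlinear regime in which the modal
#'   plate model with a quadratic membrane strain correction is valid.
#'   Relative rotation-induced strain signatures are insensitive to this
#'   scale (forcing and response both scale with it), and the absolute
#'   strain scale is absorbed by the encoder normalization.
#' @param flapping_noise_frac Noise s.d. as a fraction of the peak flapping
#'   angular velocity.
#' @return An object of class `flapping_kinematics`.
#' @export
flapping_kinematics <- function(primary_freq = 25, secondary_freq = 50,
                                secondary_rel_amplitude = 0.76,
                                peak_amplitude = 0.01,
                                flapping_noise_frac = 0.02) {
  stopifnot(primary_freq > 0, secondary_freq > 0,
            secondary_rel_amplitude >= 0, secondary_rel_amplitude <= 1,
            peak_amplitude >= 0, flapping_noise_frac >= 0)
  structure(
    list(primary_freq = primary_freq, secondary_freq = secondary_freq,
         secondary_rel_amplitude = secondary_rel_amplitude,
         peak_amplitude = peak_amplitude,
         flapping_noise_frac = flapping_noise_frac),
    class = "flapping_kinematics")
}

#' Body-rotation condition
#'
#' Constant-rate body rotation about one principal axis, superimposed on
#' flapping. Rates are comparable to those of free-flying hawkmoths
#' (10 rad/s). Rotation-rate noise defaults to 1% of the rate; for the roll
#' task no rotation noise is added because roll shares the flapping axis.
#' `disturbance_sd_frac` adds a slowly varying random rotation-rate
#' perturbation (the external-disturbance robustness probe), expressed as a
#' fraction of the 10 rad/s nominal rate and applied in both classes.
#'
#' @param axis One of `"none"`, `"yaw"`, `"pitch"`, `"roll"`.
#' @param rate Rotation rate, rad/s.
#' @param rotation_noise_frac Rate-noise s.d. as a fraction of `rate`.
#'   Defaults to 0.01, except 0 for `axis = "roll"`.
#' @param disturbance_sd_frac Disturbance s.d. as a fraction of the nominal
#'   rate (applied even when `axis = "none"`, about `disturbance_axis`).
#' @param disturbance_axis Axis the disturbance acts about; defaults to the
#'   rotation axis (must be given explicitly when `axis = "none"`).
#' @param noise_all_axes Add rotation-rate noise about all three principal
#'   axes (used by the four-way classification task).
#' @return An object of class `rotation_condition`.
#' @export
rotation_condition <- function(axis = c("none", "yaw", "pitch", "roll"),
                               rate = 10, rotation_noise_frac = NULL,
                               disturbance_sd_frac = 0,
                               disturbance_axis = NULL,
                               noise_all_axes = FALSE) {
  axis <- match.arg(axis)
  stopifnot(rate >= 0, disturbance_sd_frac >= 0)
  if (is.null(rotation_noise_frac)) {
    rotation_noise_frac <- if (axis %in% c("roll", "none")) 0 else 0.01
  }
  if (is.null(disturbance_axis)) {
    disturbance_axis <- if (axis == "none") NA_character_ else axis
  }
  if (disturbance_sd_frac > 0 && is.na(disturbance_axis)) {
    abort("disturbance_axis must be given when axis = 'none' and a disturbance is requested")
  }
  structure(
    list(axis = axis, rate = rate, rotation_noise_frac = rotation_noise_frac,
         disturbance_sd_frac = disturbance_sd_frac,
         disturbance_axis = disturbance_axis,
         noise_all_axes = isTRUE(noise_all_axes)),
    class = "rotation_condition")
}

#' Linear--nonlinear encoder parameters
#'
#' Each candidate sensor convolves local strain with a decaying-sinusoid
#' temporal filter `f(t) = cos(2 pi omega (t + tau)) exp(-(t + tau)^2 / delta^2)`
#' (omega = 1/(2 pi) per ms, tau = 5 ms, delta = 4 ms, matching wing
#' mechanosensor recordings), passes the filtered strain through a sigmoid
#' `N(g) = 1 / (1 + exp(-alpha (g - beta)))` interpreted as a per-time-step
#' firing probability, and fires probabilistically with a 15 ms absolute
#' refractory period (enforcing the observed 1--2 spikes per wingbeat).
#'
#' @param omega Filter frequency in 1/ms.
#' @param omega_scale Dimensionless multiplier on `omega` (filter-frequency
#'   sweeps).
#' @param tau Time offset of the filter peak, ms.
#' @param delta Filter decay time, ms.
#' @param alpha Sigmoid slope (sets spike-timing precision).
#' @param beta Sigmoid threshold, the filtered-strain level at half-maximum
#'   firing probability. Tested range 0.05--0.7 of the maximum filtered
#'   stimulus.
#' @param refractory Absolute refractory period, ms.
#' @param norm_constant Global scaling of filtered strain, identical for all
#'   sensors; computed from a reference simulation via
#'   [compute_norm_constant()]. `NA` until set.
#' @param discard_first_wingbeat Drop the first wingbeat (filter edge
#'   transient) from feature matrices.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(omega = 1 / (2 * pi), omega_scale = 1, tau = 5,
                           delta = 4, alpha = 50, beta = 0.2,
                           refractory = 15, norm_constant = NA_real_,
                           discard_first_wingbeat = FALSE) {
  stopifnot(omega > 0, omega_scale > 0, delta > 0, alpha > 0,
            beta > 0, beta < 1, refractory > 0)
  stopifnot(is.na(norm_constant) || norm_constant > 0)
  structure(
    list(omega = omega, omega_scale = omega_scale, tau = tau, delta = delta,
         alpha = alpha, beta = beta, refractory = refractory,
         norm_constant = norm_constant,
         discard_first_wingbeat = isTRUE(discard_first_wingbeat)),
    class = "encoder_params")
}

#' SSPOC optimization parameters
#'
#' @param m Dimension of the PCA subspace (default 3).
#' @param lam Elastic-net mixing weight between the L1 and L2 terms
#'   (default 0.9, i.e. strongly sparsity-promoting).
#' @param eps Slack of the elementwise constraint in the multi-class
#'   relaxation (default 1e-6).
#' @param k Number of sensors retained (default 10).
#' @return An object of class `sspoc_params`.
#' @export
sspoc_params <- function(m = 3, lam = 0.9, eps = 1e-6, k = 10) {
  stopifnot(m >= 1, lam >= 0, lam <= 1, eps > 0, k >= 1)
  structure(list(m = m, lam = lam, eps = eps, k = k), class = "sspoc_params")
}

#' @export
print.wing_params <- function(x, ...) {
  cat(sprintf("<wing_params> %g x %g x %g mm, E = %.3g GPa (stiffness factor %.3g)\n",
              x$span * 1e3, x$chord * 1e3, x$thickness * 1e3,
              x$youngs_modulus / 1e9, x$stiffness_factor))
  invisible(x)
}

#' @export
print.rotation_condition <- function(x, ...) {
  cat(sprintf("<rotation_condition> axis = %s, rate = %g rad/s, noise = %g%%, disturbance = %g%%\n",
              x$axis, x$rate, 100 * x$rotation_noise_frac,
              100 * x$disturbance_sd_frac))
  invisible(x)
}
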