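# Linear-nonlinear spiking encoder: strain -> filtered strain g -> firing
# probability -> probabilistic spikes with absolute refractory period ->
# time-to-first-spike per wingbeat.

#' Temporal filter kernel of the neural-inspired sensor
#'
#' Samples the decaying-sinusoid filter
#' `f(t) = cos(2 pi omega_scale omega (t + tau)) * exp(-(t + tau)^2 / delta^2)`
#' on causal lags `u = 0, -dt, ..., -(tau + 3 delta)` (the Gaussian envelope
#' is below `e^-9` beyond three decay times). The kernel peaks at 1 at lag
#' `u = -tau`, so the sensor responds to strain features peaking about 5 ms in
#' the past; applied with [filter_strain()] the convolution is strictly
#' causal.
#'
#' @param params An [encoder_params()].
#' @param dt Sampling step in seconds.
#' @return Numeric kernel vector `h`, `h[k] = f(-(k - 1) dt)`, with the lag
#'   grid (ms) in attribute `lags_ms`.
#' @export
#' @examples
#' h <- filter_kernel(encoder_params(), dt = 1e-4)
#' h[1]                      # f(0) = cos(5) exp(-25/16)
#' max(h)                    # 1 at lag -tau
filter_kernel <- function(params = encoder_params(), dt = 1e-4) {
  stopifnot(dt > 0)
  dt_ms <- dt * 1e3
  om <- params$omega * params$omega_scale
  K <- ceiling((params$tau + 3 * params$delta) / dt_ms)
  u <- -(0:K) * dt_ms
  h <- cos(2 * pi * om * (u + params$tau)) * exp(-(u + params$tau)^2 / params$delta^2)
  attr(h, "lags_ms") <- u
  h
}

# Causal FIR convolution with zero-padded history; `x` may be a vector or a
# matrix (filtered columnwise in one pass). Long multi-column inputs go
# through an FFT overlap-free full convolution for speed.
.causal_conv <- function(x, h) {
  K <- length(h) - 1
  if (is.matrix(x)) {
    if (nrow(x) * (K + 1) * ncol(x) > 2e7) {
      n <- nrow(x)
      L <- 2^ceiling(log2(n + K))
      H <- stats::fft(c(as.numeric(h), rep(0, L - K - 1)))
      Xf <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
      y <- Re(stats::mvfft(Xf * H, inverse = TRUE)) / L
      return(y[seq_len(n), , drop = FALSE])
    }
    xp <- rbind(matrix(0, K, ncol(x)), x)
    y <- stats::filter(xp, h, method = "convolution", sides = 1)
    return(matrix(as.numeric(y[(K + 1):nrow(xp), ]), ncol = ncol(x)))
  }
  xp <- c(rep(0, K), x)
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(y[(K + 1):length(xp)])
}

#' Filter a strain field through the sensor's temporal kernel
#'
#' Causal convolution of strain with the filter of [filter_kernel()], divided
#' by the global normalization constant when `params$norm_constant` is set.
#' For a `strain_field` the convolution acts on the modal time series
#' (convolution is linear), preserving the factored storage.
#'
#' @param strain A `strain_field`, or a numeric time-by-location matrix.
#' @param params An [encoder_params()].
#' @param dt Required when `strain` is a bare matrix.
#' @return Same shape as the input: a `filtered_strain` object (factored) or
#'   a numeric matrix of filtered strain g.
#' @export
filter_strain <- function(strain, params = encoder_params(), dt = NULL) {
  nc <- if (is.na(params$norm_constant)) 1 else params$norm_constant
  if (inherits(strain, "strain_field")) {
    h <- filter_kernel(params, strain$dt)
    qf <- .causal_conv(strain$q, h) / nc
    out <- strain
    out$q <- qf
    class(out) <- c("filtered_strain", "strain_field")
    return(out)
  }
  x <- as.matrix(strain)
  if (is.null(dt)) abort("dt must be supplied when filtering a bare matrix")
  h <- filter_kernel(params, dt)
  .causal_conv(x, h) / nc
}

#' Normalization constant from a reference simulation
#'
#' The filtered strain g is scaled by one constant, identical for all
#' sensors, chosen so that the maximum |g| over all sensors and times equals
#' exactly 1 for the reference condition (3 GPa wing, flapping only). The
#' same constant is reused for every stiffness and rotation condition, so the
#' threshold beta is expressed as a fraction of the reference maximum
#' filtered stimulus.
#'
#' @param strain_ref A `strain_field` simulated at the reference stiffness,
#'   flapping-only condition.
#' @param params An [encoder_params()] (its `norm_constant` is ignored).
#' @param block Locations per block when scanning the field.
#' @return The scalar normalization constant (max |g| of the unnormalized
#'   reference).
#' @export
compute_norm_constant <- function(strain_ref, params = encoder_params(),
                                  block = 256) {
  params$norm_constant <- NA_real_
  g <- filter_strain(strain_ref, params)
  pk <- strain_peak(g, block = block)
  if (pk <= 0) abort("reference strain field is identically zero; cannot normalize")
  pk
}

#' Static nonlinearity: filtered strain to firing probability
#'
#' Elementwise sigmoid `N(g) = 1 / (1 + exp(-alpha (g - beta)))`: the
#' per-time-step probability that the sensor fires. `beta` is the threshold
#' (half-maximum point), `alpha` the slope setting spike-timing precision.
#'
#' @param g Numeric vector/matrix of (normalized) filtered strain.
#' @param params An [encoder_params()].
#' @return Firing probabilities, same shape as `g`, in (0, 1).
#' @export
nonlinearity <- function(g, params = encoder_params()) {
  1 / (1 + exp(-params$alpha * (g - params$beta)))
}

#' Generate probabilistic spike trains
#'
#' At each time step the sensor spikes if the firing probability exceeds a
#' standard-uniform draw, subject to a 15 ms absolute refractory period: after
#' a spike at time t, the next spike is permitted at times >= t + refractory
#' (closed boundary).
#'
#' @param p Firing-probability matrix (time by locations).
#' @param refractory Refractory period, ms.
#' @param n_repeats Number of independent spike-train realizations.
#' @param seed Integer seed (draws ordered location-major, then repeat, then
#'   time).
#' @param dt Time step, seconds.
#' @return A `spike_raster`: binary array (time x locations x repeats).
#' @export
generate_spikes <- function(p, refractory = 15, n_repeats = 1, seed = 1,
                            dt = 1e-4) {
  p <- as.matrix(p)
  stopifnot(all(p >= 0), all(p <= 1), n_repeats >= 1)
  refr_steps <- round(refractory / (dt * 1e3))
  x <- with_seed(seed, gen_spikes_cpp(p, refr_steps, n_repeats))
  structure(list(data = array(x, dim = c(nrow(p), ncol(p), n_repeats)),
                 dt = dt, refractory = refractory, seed = seed),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spike_raster> %d steps x %d locations x %d repeats, %d spikes total\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Time-to-first-spike features per wingbeat
#'
#' For each wingbeat, repeat and location, the time from wingbeat onset to
#' the first spike, quantized to the 0.1 ms sampling grid; 0 encodes "no
#' spike in this wingbeat". A spike landing exactly on the wingbeat-onset
#' sample reports one time step (keeping 0 unambiguous). Rows are ordered
#' repeat-major (all wingbeats of repeat 1, then repeat 2, ...).
#'
#' @param raster A [generate_spikes()] result.
#' @param wingbeat_period Wingbeat period, ms (default 40).
#' @return A `spike_features` object; the feature matrix has
#'   `wingbeats * repeats` rows and one column per location.
#' @export
first_spike_features <- function(raster, wingbeat_period = 40) {
  dt_ms <- raster$dt * 1e3
  wb_steps <- round(wingbeat_period / dt_ms)
  d <- dim(raster$data)
  n_wb <- d[1] %/% wb_steps
  if (n_wb < 1) abort("raster shorter than one wingbeat")
  n <- d[2]; n_reps <- d[3]
  fs <- matrix(0, n_wb * n_reps, n)
  for (r in seq_len(n_reps)) {
    sl <- raster$data[seq_len(n_wb * wb_steps), , r, drop = FALSE]
    dim(sl) <- c(wb_steps, n_wb, n)
    for (wb in seq_len(n_wb)) {
      blk <- sl[, wb, ]
      if (n == 1) blk <- matrix(blk, ncol = 1)
      first <- apply(blk, 2, function(cc) {
        w <- which(cc > 0)
        if (length(w)) max((w[1] - 1) * dt_ms, dt_ms) else 0
      })
      fs[(r - 1) * n_wb + wb, ] <- first
    }
  }
  new_spike_features(fs, n_wb = n_wb, n_reps = n_reps, dt_ms = dt_ms,
                     period_ms = wingbeat_period)
}

new_spike_features <- function(features, n_wb, n_reps, dt_ms, period_ms,
                               label = NULL, counts = NULL) {
  structure(
    list(features = features, label = label,
         wingbeat = rep(rep(seq_len(n_wb), times = n_reps),
                        length.out = nrow(features)),
         rep = rep(rep(seq_len(n_reps), each = n_wb),
                   length.out = nrow(features)),
         n_wb = n_wb, n_reps = n_reps, dt_ms = dt_ms, period_ms = period_ms,
         counts = counts),
    class = "spike_features")
}

#' @export
print.spike_features <- function(x, ...) {
  cat(sprintf("<spike_features> %d observations x %d locations (%d wingbeats x %d repeats)",
              nrow(x$features), ncol(x$features), x$n_wb, x$n_reps))
  if (!is.null(x$label)) cat(sprintf("; classes: %s", paste(levels(x$label), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Encode a strain field end to end
#'
#' Fast path from a `strain_field` to first-spike features: filters the modal
#' time series once, then streams location blocks through the compiled
#' spike-generation kernel without materializing the full probability array.
#' Results are identical to composing [filter_strain()], [nonlinearity()],
#' [generate_spikes()] and [first_spike_features()] with the same seed.
#'
#' @param field A `strain_field`.
#' @param params An [encoder_params()] with `norm_constant` set (see
#'   [compute_norm_constant()]).
#' @param n_repeats Spike-train realizations per simulation (default 10).
#' @param seed Integer seed.
#' @param block Locations per block.
#' @return A `spike_features` object (with per-repeat spike counts in
#'   `$counts`).
#' @export
encode_strain <- function(field, params = encoder_params(), n_repeats = 10,
                          seed = 1, block = 256) {
  dt_ms <- field$dt * 1e3
  period_ms <- 1e3 / field$kin$primary_freq
  wb_steps <- round(period_ms / dt_ms)
  n_wb <- field$n_time %/% wb_steps
  refr_steps <- round(params$refractory / dt_ms)

  if (inherits(field, "filtered_strain")) {
    qf <- field$q  # already filtered and normalized
  } else {
    if (is.na(params$norm_constant)) {
      abort("params$norm_constant is not set; compute it from a reference simulation with compute_norm_constant()")
    }
    h <- filter_kernel(params, field$dt)
    qf <- .causal_conv(field$q, h) / params$norm_constant
  }

  n <- field$n_locations
  fs <- matrix(0, n_wb * n_repeats, n)
  counts <- matrix(0L, n_repeats, n)
  with_seed(seed, {
    for (st in seq(1, n, by = block)) {
      idx <- st:min(st + block - 1, n)
      g <- qf %*% t(field$S[idx, , drop = FALSE])
      res <- ln_encode_cpp(g, params$alpha, params$beta, refr_steps,
                           wb_steps, n_wb, n_repeats, dt_ms)
      fs[, idx] <- res$first_spike
      counts[, idx] <- res$counts
    }
  })
  out <- new_spike_features(fs, n_wb = n_wb, n_reps = n_repeats,
                            dt_ms = dt_ms, period_ms = period_ms,
                            counts = counts)
  if (params$discard_first_wingbeat) out <- drop_first_wingbeat(out)
  out
}

# Spike-encode a precomputed (filtered, normalized) g matrix. Used by the
# sweep driver, which materializes g once per strain field and reuses it
# across neural thresholds.
encode_g <- function(G, params, n_repeats, seed, dt_ms, period_ms,
                     block = 256) {
  wb_steps <- round(period_ms / dt_ms)
  n_wb <- nrow(G) %/% wb_steps
  refr_steps <- round(params$refractory / dt_ms)
  res <- with_seed(seed,
    ln_encode_cpp(G, params$alpha, params$beta, refr_steps, wb_steps,
                  n_wb, n_repeats, dt_ms))
  out <- new_spike_features(res$first_spike, n_wb = n_wb, n_reps = n_repeats,
                            dt_ms = dt_ms, period_ms = period_ms,
                            counts = res$counts)
  if (params$discard_first_wingbeat) out <- drop_first_wingbeat(out)
  out
}

drop_first_wingbeat <- function(sf) {
  keep <- sf$wingbeat != 1
  sf$features <- sf$features[keep, , drop = FALSE]
  if (!is.null(sf$label)) sf$label <- sf$label[keep]
  sf$wingbeat <- sf$wingbeat[keep] - 1L
  sf$rep <- sf$rep[keep]
  sf$n_wb <- sf$n_wb - 1L
  sf
}

#' Stack per-condition feature sets into one labelled data set
#'
#' @param feature_list List of `spike_features`, one per condition.
#' @param labels Character vector of condition labels, same length.
#' @return A labelled `spike_features` with all observations stacked.
#' @export
bind_features <- function(feature_list, labels) {
  stopifnot(length(feature_list) == length(labels))
  feats <- do.call(rbind, lapply(feature_list, `[[`, "features"))
  lab <- factor(rep(labels, vapply(feature_list, function(f) nrow(f$features), 1L)),
                levels = labels)
  f1 <- feature_list[[1]]
  out <- new_spike_features(feats, n_wb = f1$n_wb, n_reps = f1$n_reps,
                            dt_ms = f1$dt_ms, period_ms = f1$period_ms,
                            label = lab)
  out$wingbeat <- unlist(lapply(feature_list, `[[`, "wingbeat"))
  out$rep <- unlist(lapply(feature_list, `[[`, "rep"))
  out
}

#' Median spikes per wingbeat across active sensors
#'
#' A sensor is active if it fired at least once. With default parameters at
#' the reference stiffness this lands in the observed 1--2 spikes per
#' wingbeat range.
#'
#' @param sf A `spike_features` from [encode_strain()] (needs `$counts`).
#' @return Scalar median spikes per wingbeat per active sensor.
#' @export
spikes_per_wingbeat <- function(sf) {
  if (is.null(sf$counts)) abort("spike counts unavailable; encode with encode_strain()")
  per_wb <- colMeans(sf$counts) / sf$n_wb
  median(per_wb[per_wb > 0])
}

#' @export
tidy.spike_features <- function(x, ...) {
  tb <- tibble::as_tibble(x$features, .name_repair = function(n) {
    paste0("loc", seq_along(n))
  })
  out <- tibble::tibble(
    observation = seq_len(nrow(tb)),
    wingbeat = x$wingbeat,
    rep = x$rep)
  if (!is.null(x$label)) out$label <- x$label
  dplyr::bind_cols(out, tb)
}
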