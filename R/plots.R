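# ggplot2 autoplot methods for the main result types.

#' @describeIn run_sweep Heatmap of mean accuracy (or mean spanwise sensor
#'   location) over the stiffness-by-threshold grid.
#' @param object An `accuracy_map`.
#' @param fill `"accuracy"` or `"span"`.
#' @param ... Unused.
#' @export
autoplot.accuracy_map <- function(object, fill = c("accuracy", "span"), ...) {
  fill <- match.arg(fill)
  sm <- summarize_map(object)
  if (fill == "accuracy") {
    ggplot2::ggplot(sm, ggplot2::aes(factor(round(.data$stiffness_factor, 3)),
                                     factor(round(.data$beta, 3)),
                                     fill = .data$mean_accuracy)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "accuracy") +
      ggplot2::labs(x = "stiffness factor (1 = 3 GPa)", y = "neural threshold beta")
  } else {
    ggplot2::ggplot(sm, ggplot2::aes(factor(round(.data$stiffness_factor, 3)),
                                     factor(round(.data$beta, 3)),
                                     fill = .data$mean_span_frac)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "inferno",
                                    name = "span fraction\n(0 = base)") +
      ggplot2::labs(x = "stiffness factor (1 = 3 GPa)", y = "neural threshold beta")
  }
}

#' @describeIn solve_sensors_2class Wing-planform map of sensor weights with
#'   the selected top-k highlighted.
#' @param object A `sensor_weights`.
#' @param grid The [sensor_grid()] the weights refer to.
#' @param ... Unused.
#' @export
autoplot.sensor_weights <- function(object, grid = sensor_grid(), ...) {
  tb <- tidy(object, grid = grid)
  ggplot2::ggplot(tb, ggplot2::aes(.data$span_mm, .data$chord_mm)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$weight)) +
    ggplot2::geom_point(data = dplyr::filter(tb, .data$selected),
                        colour = "red", size = 1.6) +
    ggplot2::scale_fill_viridis_c(name = "|weight|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "spanwise (mm, 0 = base)", y = "chordwise (mm, 0 = leading edge)")
}

#' @describeIn dropout_analysis Accuracy versus number of retained sensors.
#' @param object A `dropout_result`.
#' @param ... Unused.
#' @export
autoplot.dropout_result <- function(object, ...) {
  sm <- object |>
    dplyr::group_by(.data$n_keep) |>
    dplyr::summarise(mean = mean(.data$accuracy), sd = sd(.data$accuracy),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(.data$n_keep, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(sm$n_keep)) +
    ggplot2::labs(x = "sensors retained", y = "accuracy")
}

#' @describeIn disturbance_analysis Accuracy versus disturbance magnitude.
#' @param object A `disturbance_result`.
#' @param ... Unused.
#' @export
autoplot.disturbance_result <- function(object, ...) {
  sm <- object |>
    dplyr::group_by(.data$sd_frac) |>
    dplyr::summarise(mean = mean(.data$accuracy), sd = sd(.data$accuracy),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(100 * .data$sd_frac, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "disturbance s.d. (% of rotation rate)", y = "accuracy")
}

#' @describeIn simulate_strain Strain traces at selected locations.
#' @param object A `strain_field`.
#' @param locations Location indices to draw (default: the four corners).
#' @param ... Unused.
#' @export
autoplot.strain_field <- function(object, locations = NULL, ...) {
  if (is.null(locations)) locations <- grid_corners(object$grid)
  tb <- tidy(object, locations = locations)
  ggplot2::ggplot(tb, ggplot2::aes(.data$time_s, .data$strain,
                                   colour = factor(.data$location))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "surface strain", colour = "location")
}
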