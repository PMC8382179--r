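#' Candidate sensor grid on the wing planform
#'
#' Candidate sensor locations lie on a regular lattice over the plate:
#' 51 spanwise positions (wing base, 0 mm, to wing tip, 50 mm) by
#' 26 chordwise positions (leading edge, 0 mm, to trailing edge, 25 mm) at
#' 1 mm spacing, 1,326 locations in all.
#'
#' Location ordering is spanwise-major and used consistently everywhere:
#' the chordwise index varies fastest, so location 1 is the base
#' leading-edge corner and location 1326 the tip trailing-edge corner.
#'
#' @param spanwise_count,chordwise_count Number of lattice points along each
#'   direction.
#' @param span,chord Plate dimensions in metres.
#' @return An object of class `sensor_grid`.
#' @export
#' @examples
#' g <- sensor_grid()
#' nrow(grid_coordinates(g))  # 1326
sensor_grid <- function(spanwise_count = 51, chordwise_count = 26,
                        span = 50e-3, chord = 25e-3) {
  stopifnot(spanwise_count >= 2, chordwise_count >= 2, span > 0, chord > 0)
  structure(
    list(spanwise_count = spanwise_count, chordwise_count = chordwise_count,
         span = span, chord = chord,
         n_locations = spanwise_count * chordwise_count),
    class = "sensor_grid")
}

#' Physical coordinates of every candidate location
#'
#' @param grid A [sensor_grid()].
#' @return A tibble with one row per location in grid order: `location`
#'   (index), `span_mm` (0 = base), `chord_mm` (0 = leading edge), and the
#'   dimensionless fractions `span_frac`, `chord_frac`.
#' @export
grid_coordinates <- function(grid = sensor_grid()) {
  span_idx <- rep(seq_len(grid$spanwise_count), each = grid$chordwise_count)
  chord_idx <- rep(seq_len(grid$chordwise_count), times = grid$spanwise_count)
  span_frac <- (span_idx - 1) / (grid$spanwise_count - 1)
  chord_frac <- (chord_idx - 1) / (grid$chordwise_count - 1)
  tibble::tibble(
    location = seq_len(grid$n_locations),
    span_mm = span_frac * grid$span * 1e3,
    chord_mm = chord_frac * grid$chord * 1e3,
    span_frac = span_frac,
    chord_frac = chord_frac)
}

#' Indices of the four wing-corner grid nodes
#'
#' @param grid A [sensor_grid()].
#' @return Integer vector: base/leading, base/trailing, tip/leading,
#'   tip/trailing corners.
#' @export
grid_corners <- function(grid = sensor_grid()) {
  nc <- grid$chordwise_count
  n <- grid$n_locations
  c(1L, nc, n - nc + 1L, n)
}

#' Location mask helpers for region-restricted sensor selection
#'
#' Returns the location indices belonging to the proximal (base) or distal
#' (tip) half of the wing, for use as candidate masks during selection.
#'
#' @param grid A [sensor_grid()].
#' @param region `"proximal"` or `"distal"`.
#' @return Integer vector of location indices.
#' @export
grid_region <- function(grid = sensor_grid(), region = c("proximal", "distal")) {
  region <- match.arg(region)
  co <- grid_coordinates(grid)
  if (region == "proximal") which(co$span_frac <= 0.5) else which(co$span_frac > 0.5)
}

#' @export
print.sensor_grid <- function(x, ...) {
  cat(sprintf("<sensor_grid> %d spanwise x %d chordwise = %d locations (%g x %g mm)\n",
              x$spanwise_count, x$chordwise_count, x$n_locations,
              x$span * 1e3, x$chord * 1e3))
  invisible(x)
}
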