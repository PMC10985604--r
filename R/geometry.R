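#' Obstacle-course geometry
#'
#' Describes the 6.5 m walkway and the four obstacles in the canonical lab
#' frame: +X is the walking direction, +Z is up, the floor is z = 0 and the
#' origin sits at the walkway start.  All lengths are metres.
#'
#' Defaults reproduce the course used in the validation study: a 15 cm high
#' bar to overstep, a 50 cm gap to cross, a 20 cm wide beam corridor to
#' balance along, and four slalom poles spaced 56 cm apart (about 1.7 times
#' the average child shoulder width) to circumvent.  The pole diameter was
#' not reported, so `pole_radius` stays configurable.
#'
#' @param walkway_length Walkway length along +X (m).
#' @param bar_position Forward position of the overstepping bar (m).
#' @param bar_height Bar height (m).
#' @param gap_start Forward position of the near gap edge (m).
#' @param gap_width Gap width (m).
#' @param beam_start Forward position where the beam corridor begins (m).
#' @param beam_length Length of the beam corridor (m).
#' @param beam_center_y Lateral centre of the beam corridor (m).
#' @param beam_width Beam corridor width (m).
#' @param pole_positions Two-column matrix (x, y) of pole centres; by default
#'   four poles on the walkway midline starting at `pole_start`, spaced
#'   `pole_spacing` apart.
#' @param pole_start Forward position of the first pole (m), used only when
#'   `pole_positions` is not supplied.
#' @param pole_spacing Distance between consecutive poles (m).
#' @param pole_radius Pole radius (m).
#' @param task_zone_margin Entry/exit margin around each obstacle's extent
#'   that defines the timing gate for task total time (m).
#' @return A `course_geometry` list.
#' @export
course_geometry <- function(walkway_length = 6.5,
                            bar_position = 3.0,
                            bar_height = 0.15,
                            gap_start = 3.0,
                            gap_width = 0.50,
                            beam_start = 2.5,
                            beam_length = 2.0,
                            beam_center_y = 0,
                            beam_width = 0.20,
                            pole_positions = NULL,
                            pole_start = 2.6,
                            pole_spacing = 0.56,
                            pole_radius = 0.025,
                            task_zone_margin = 1.0) {
  if (is.null(pole_positions)) {
    pole_positions <- cbind(x = pole_start + (0:3) * pole_spacing, y = 0)
  }
  pole_positions <- as.matrix(pole_positions)
  if (ncol(pole_positions) != 2L) stopf("pole_positions must have columns (x, y)")
  g <- structure(list(
    walkway_length = walkway_length,
    bar_position = bar_position, bar_height = bar_height,
    gap_start = gap_start, gap_width = gap_width,
    beam_start = beam_start, beam_length = beam_length,
    beam_center_y = beam_center_y, beam_width = beam_width,
    pole_positions = pole_positions, pole_spacing = pole_spacing,
    pole_radius = pole_radius,
    task_zone_margin = task_zone_margin
  ), class = "course_geometry")
  validate_geometry(g)
}

#' @noRd
validate_geometry <- function(g) {
  num <- c("walkway_length", "bar_position", "bar_height", "gap_start",
           "gap_width", "beam_start", "beam_length", "beam_width",
           "pole_spacing", "pole_radius", "task_zone_margin")
  for (f in num) {
    if (!is_number(g[[f]]) || g[[f]] <= 0) stopf("geometry field '%s' must be a positive number", f)
  }
  if (!is_number(g$beam_center_y)) stopf("beam_center_y must be a number")
  L <- g$walkway_length
  inside <- c(g$bar_position, g$gap_start, g$gap_start + g$gap_width,
              g$beam_start, g$beam_start + g$beam_length, g$pole_positions[, 1])
  if (any(inside <= 0) || any(inside >= L)) {
    stopf("all obstacles must lie strictly within the %.2f m walkway", L)
  }
  px <- sort(g$pole_positions[, 1])
  if (nrow(g$pole_positions) > 1) {
    dd <- diff(px)
    if (any(abs(dd - g$pole_spacing) > 1e-9)) {
      stopf("pole_positions are not spaced pole_spacing = %.3f m apart", g$pole_spacing)
    }
  }
  g
}

# Forward extent [x_min, x_max] of a task's obstacle (zero width for the bar;
# whole walkway for unobstructed walking).
#' @noRd
obstacle_extent <- function(geometry, task) {
  switch(task,
    normal_walking = c(0, geometry$walkway_length),
    overstepping   = rep(geometry$bar_position, 2),
    crossing       = c(geometry$gap_start, geometry$gap_start + geometry$gap_width),
    balancing      = c(geometry$beam_start, geometry$beam_start + geometry$beam_length),
    circumventing  = range(geometry$pole_positions[, 1]),
    stopf("unknown task '%s'", task))
}

# Timing gate [entry, exit] for total task time.
#' @noRd
task_zone <- function(geometry, task) {
  ext <- obstacle_extent(geometry, task)
  if (task == "normal_walking") return(ext)
  c(ext[1] - geometry$task_zone_margin, ext[2] + geometry$task_zone_margin)
}

#' @export
print.course_geometry <- function(x, ...) {
  cat("<course_geometry>\n")
  cat(sprintf("  walkway %.2f m; bar at %.2f m (h %.2f m); gap [%.2f, %.2f] m\n",
              x$walkway_length, x$bar_position, x$bar_height,
              x$gap_start, x$gap_start + x$gap_width))
  cat(sprintf("  beam [%.2f, %.2f] m (width %.2f m); %d poles (r %.3f m) at x = %s\n",
              x$beam_start, x$beam_start + x$beam_length, x$beam_width,
              nrow(x$pole_positions), x$pole_radius,
              paste(sprintf("%.2f", x$pole_positions[, 1]), collapse = ", ")))
  invisible(x)
}
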