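#' Describe a fixation-grid stimulus and its viewing geometry
#'
#' The grid design presents `n_rows * n_cols` stimulus points one at a
#' time on a screen at a known distance from the participant's eyes.
#' Physical spacings plus the viewing distance determine the angular
#' separation between adjacent points, the yardstick against which
#' estimated gaze separations are judged.
#'
#' @param n_cols,n_rows Grid dimensions (default 3 x 3).
#' @param dx_cm Horizontal spacing between adjacent points, cm
#'   (default 18.6).
#' @param dy_cm Vertical spacing between adjacent points, cm
#'   (default 11.6).
#' @param screen_distance_cm Eye-to-screen-center distance, cm
#'   (default 95).
#' @param camera_distance_cm Eye-to-camera distance, cm; metadata only
#'   (default 85).
#'
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_cols = 3L, n_rows = 3L, dx_cm = 18.6, dy_cm = 11.6,
                      screen_distance_cm = 95, camera_distance_cm = 85) {
  stopifnot(dx_cm > 0, dy_cm > 0, screen_distance_cm > 0,
            camera_distance_cm > 0, n_cols >= 2L, n_rows >= 2L)
  structure(
    list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         dx_cm = dx_cm, dy_cm = dy_cm,
         screen_distance_cm = screen_distance_cm,
         camera_distance_cm = camera_distance_cm),
    class = "grid_spec"
  )
}

#' Angular separation between adjacent grid points
#'
#' Converts the physical point spacing into degrees of visual angle via
#' a single arctangent of spacing over viewing distance, taken from the
#' screen center.  With the default geometry (18.6 cm / 11.6 cm spacing
#' at 95 cm) the separations are about 11 and 7 degrees.  Per-pair
#' eccentricity effects are deliberately not modeled: one value per
#' axis.
#'
#' @param grid A [grid_spec()].
#' @return Named numeric vector `c(horizontal = ..., vertical = ...)`
#'   in degrees.
#' @export
grid_angles <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  c(horizontal = deg(atan(grid$dx_cm / grid$screen_distance_cm)),
    vertical   = deg(atan(grid$dy_cm / grid$screen_distance_cm)))
}

#' True gaze angles of each grid point
#'
#' Points are enumerated row-major in presentation order (left-to-right,
#' top-to-bottom).  Angles follow the canonical sign convention:
#' rightward and upward of screen center positive, each coordinate a
#' single arctangent of its centered physical offset over the viewing
#' distance.
#'
#' @param grid A [grid_spec()].
#' @return Tibble with columns `point`, `row`, `col`, `theta_x`,
#'   `theta_y` (degrees).
#' @export
grid_point_angles <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- seq_len(grid$n_rows)
  cols <- seq_len(grid$n_cols)
  g <- expand.grid(col = cols, row = rows)   # row-major: col varies fastest
  x_cm <- (g$col - (grid$n_cols + 1) / 2) * grid$dx_cm
  y_cm <- ((grid$n_rows + 1) / 2 - g$row) * grid$dy_cm  # row 1 at top
  tibble::tibble(
    point = seq_len(nrow(g)),
    row = g$row, col = g$col,
    theta_x = deg(atan(x_cm / grid$screen_distance_cm)),
    theta_y = deg(atan(y_cm / grid$screen_distance_cm))
  )
}
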