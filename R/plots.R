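#' Scatter plot of a grid session's gaze configuration
#'
#' The visual check of configuration accuracy: horizontal against
#' vertical gaze estimates, colored by stimulus-point row with shade by
#' column.  Nine separable clusters arranged like the stimulus grid
#' indicate good configuration accuracy.
#'
#' @param blocks List of per-point [gaze_recording()]s (row-major).
#' @param grid The session's [grid_spec()] (for row/column lookup).
#' @return A ggplot object.
#' @export
plot_grid_configuration <- function(blocks, grid = grid_spec()) {
  pts <- grid_point_angles(grid)
  d <- dplyr::bind_rows(lapply(seq_along(blocks), function(p) {
    s <- blocks[[p]]$samples
    s <- s[s$valid, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    tibble::tibble(x = s$x, y = s$y, row = factor(pts$row[p]),
                   col = pts$col[p])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$row,
                                  alpha = .data$col)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_alpha(range = c(0.35, 1), guide = "none") +
    ggplot2::labs(x = "horizontal gaze estimate", y = "vertical gaze estimate",
                  color = "grid row") +
    ggplot2::theme_minimal()
}

#' Histogram and AOI sections of horizontal gaze angles
#'
#' Shows the session's horizontal gaze histogram with the smoothed
#' density and the inferred AOI sections shaded, the visual companion
#' to [segment_aois()].
#'
#' @param histogram A [build_histogram()] result.
#' @param seg The matching [segment_aois()] result.
#' @return A ggplot object.
#' @export
plot_aoi_histogram <- function(histogram, seg) {
  hd <- tibble::tibble(mid = histogram$mids, count = histogram$counts)
  p <- ggplot2::ggplot(hd, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = histogram$bin_width, fill = "grey70") +
    ggplot2::geom_line(data = seg$density,
                       ggplot2::aes(x = .data$x, y = .data$d),
                       color = "black") +
    ggplot2::labs(x = "horizontal gaze angle (deg)", y = "samples per bin") +
    ggplot2::theme_minimal()
  if (!seg$excluded) {
    p <- p + ggplot2::geom_rect(
      data = seg$sections, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = 0, ymax = Inf,
                   fill = .data$aoi), alpha = 0.25) +
      ggplot2::labs(fill = "AOI")
  }
  p
}

#' Paired per-participant comparison of looking measures
#'
#' Per AOI, the estimator-derived and manually coded values of one
#' measure for every participant, joined by grey lines; horizontal
#' bars mark the per-method medians.
#'
#' @param est,man Stacked per-subject measure tibbles as passed to
#'   [compare_measures()].
#' @param measure `"relative_total"` or `"mean_duration"`.
#' @return A ggplot object.
#' @export
plot_paired_measures <- function(est, man, measure = c("relative_total",
                                                       "mean_duration")) {
  measure <- match.arg(measure)
  d <- dplyr::bind_rows(
    dplyr::mutate(est, method = "estimates"),
    dplyr::mutate(man, method = "manual")
  )
  d$value <- d[[measure]]
  d$aoi <- factor(d$aoi, levels = aoi_labels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       color = "grey70", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(color = .data$method), size = 1.5) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~aoi, nrow = 1) +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = NULL,
                  y = if (measure == "relative_total")
                        "relative total dwell time"
                      else "mean dwell duration (s)") +
    ggplot2::theme_minimal()
}
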