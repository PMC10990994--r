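#' Per-fixation median gaze positions
#'
#' The robust location estimate underlying both the scale-ratio and
#' precision statistics: the median horizontal and vertical gaze
#' estimate over the valid samples of each fixation block.
#'
#' @param blocks List of [gaze_recording()]s, one per stimulus point in
#'   row-major order.
#' @return Tibble with columns `point`, `median_x`, `median_y`,
#'   `n_valid`.  Blocks without any valid sample get `NA` medians and a
#'   warning; downstream statistics exclude them.
#' @export
fixation_medians <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  out <- lapply(seq_along(blocks), function(p) {
    s <- blocks[[p]]$samples
    v <- s[s$valid, , drop = FALSE]
    if (nrow(v) == 0L) {
      tibble::tibble(point = p, median_x = NA_real_, median_y = NA_real_,
                     n_valid = 0L)
    } else {
      tibble::tibble(point = p, median_x = median(v$x), median_y = median(v$y),
                     n_valid = nrow(v))
    }
  })
  out <- dplyr::bind_rows(out)
  if (any(out$n_valid == 0L)) {
    warning(sprintf("%d fixation block(s) without valid samples excluded",
                    sum(out$n_valid == 0L)), call. = FALSE)
  }
  out
}

# Pairs of points that are axis-adjacent on a grid: for axis = "x" the
# horizontally adjacent pairs within each row, for axis = "y" the
# vertically adjacent pairs within each column.  Points are numbered
# row-major.
adjacent_pairs <- function(grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  nr <- grid$n_rows; nc <- grid$n_cols
  idx <- function(row, col) (row - 1L) * nc + col
  pairs <- list()
  if (axis == "x") {
    for (r in seq_len(nr)) for (cc in seq_len(nc - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(idx(r, cc), idx(r, cc + 1L))
    }
  } else {
    for (cc in seq_len(nc)) for (r in seq_len(nr - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(idx(r, cc), idx(r + 1L, cc))
    }
  }
  do.call(rbind, pairs)
}

# Median absolute separation of fixation medians over axis-adjacent
# pairs; NA medians drop their pairs.
median_adjacent_separation <- function(medians, grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  pr <- adjacent_pairs(grid, axis)
  m <- if (axis == "x") medians$median_x else medians$median_y
  seps <- abs(m[pr[, 1]] - m[pr[, 2]])
  seps <- seps[!is.na(seps)]
  if (length(seps) < 2L) {
    stop("fewer than 2 defined adjacent pairs on axis ", axis, call. = FALSE)
  }
  median(seps)
}

#' Scale-ratio accuracy of a grid session
#'
#' The median angular separation between axis-adjacent fixation medians
#' divided by the grid's true angular separation on that axis.  A ratio
#' of 1 means the estimates reproduce the stimulus grid's scale
#' faithfully; ratios below 1 indicate under-estimation (the estimated
#' grid is compressed), above 1 over-estimation.  The ratio is invariant
#' to additive offsets, so it is meaningful even when the estimator's
#' absolute origin is unknown.
#'
#' @param medians Output of [fixation_medians()].
#' @param grid The [grid_spec()] the session was recorded against.
#' @param axis `"x"` or `"y"`.
#' @return Dimensionless ratio.
#' @export
scale_ratio <- function(medians, grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  sep <- median_adjacent_separation(medians, grid, axis)
  ga <- grid_angles(grid)
  sep / unname(ga[if (axis == "x") "horizontal" else "vertical"])
}

#' Spread-to-separation precision ratio
#'
#' The median within-fixation standard deviation of the gaze signal on
#' one axis, divided by the median separation between axis-adjacent
#' fixation medians on that axis.  A ratio near zero means fixations on
#' distinct points are clearly distinguishable; higher values mean the
#' within-fixation spread rivals the between-fixation separation and
#' overlap is likely.  Because numerator and denominator share units,
#' the ratio is comparable across angle-valued and normalized-coordinate
#' estimators and is invariant to any affine rescaling applied to the
#' whole recording.
#'
#' @param blocks List of [gaze_recording()]s, one per stimulus point.
#' @param grid The session's [grid_spec()].
#' @param axis `"x"` or `"y"`.
#' @return Dimensionless ratio.
#' @export
precision_ratio <- function(blocks, grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  sds <- vapply(blocks, function(b) {
    s <- b$samples
    vals <- if (axis == "x") s$x[s$valid] else s$y[s$valid]
    if (length(vals) < 2L) NA_real_ else sd(vals)
  }, numeric(1))
  if (anyNA(sds)) {
    warning(sprintf("%d block(s) with < 2 valid samples excluded from spread",
                    sum(is.na(sds))), call. = FALSE)
    sds <- sds[!is.na(sds)]
  }
  if (!length(sds)) stop("no block with >= 2 valid samples", call. = FALSE)
  med <- fixation_medians(blocks)
  sep <- median_adjacent_separation(med, grid, axis)
  if (sep == 0) {
    stop("median adjacent separation is zero: degenerate configuration",
         call. = FALSE)
  }
  median(sds) / sep
}

#' Percentage of lost samples
#'
#' Data loss is the share of samples with a missing gaze estimate, in
#' percent of all samples.
#'
#' @param x A [gaze_recording()] or a list of them.
#' @return Percent in `[0, 100]`.
#' @export
data_loss <- function(x) {
  if (inherits(x, "gaze_recording")) x <- list(x)
  stopifnot(is.list(x), length(x) >= 1L)
  valid <- unlist(lapply(x, function(r) r$samples$valid))
  if (!length(valid)) stop("no samples", call. = FALSE)
  100 * mean(!valid)
}

#' Flag candidate blink intervals from vertical gaze velocity
#'
#' Calibration-free estimators keep reporting gaze while the eyes are
#' closed, so blinks show up not as data loss but as sharp transients on
#' the vertical channel.  This heuristic flags intervals where the
#' absolute vertical velocity between consecutive valid samples exceeds
#' a threshold, merging flags closer together than `min_separation`
#' (a blink produces one spike at lid closure and one at re-opening).
#'
#' @param rec A [gaze_recording()] with at least 2 valid samples.
#' @param velocity_threshold Threshold in signal units per second
#'   (degrees/s for angle sources); must be positive.  The default 200
#'   sits well above fixation noise at 60 Hz and well below the slope of
#'   a multi-degree transient traversed within a frame.
#' @param min_separation Merge distance in seconds (default 0.2, long enough to merge the closure and reopening spikes of one blink).
#' @return Tibble with columns `start`, `end` (seconds); zero rows when
#'   nothing exceeds the threshold.
#' @export
flag_blinks <- function(rec, velocity_threshold = 200, min_separation = 0.2) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (velocity_threshold <= 0) {
    stop("velocity_threshold must be positive", call. = FALSE)
  }
  s <- rec$samples[rec$samples$valid, , drop = FALSE]
  if (nrow(s) < 2L) stop("need at least 2 valid samples", call. = FALSE)
  v <- abs(diff(s$y) / diff(s$t))
  hit <- which(v > velocity_threshold)
  if (!length(hit)) return(tibble::tibble(start = numeric(), end = numeric()))
  iv <- cbind(start = s$t[hit], end = s$t[hit + 1L])
  merged <- list(iv[1L, ])
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- merged[[length(merged)]]
    if (iv[i, "start"] - last["end"] < min_separation) {
      last["end"] <- max(last["end"], iv[i, "end"])
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- iv[i, ]
    }
  }
  m <- do.call(rbind, merged)
  tibble::tibble(start = unname(m[, "start"]), end = unname(m[, "end"]))
}

#' Full data-quality report for one grid session
#'
#' Bundles the session-level quality statistics: scale ratios and
#' precision ratios per axis, data-loss percentage, per-fixation
#' medians, and flagged blink intervals (pooled across blocks).
#'
#' @param blocks List of per-point [gaze_recording()]s.
#' @param grid The session's [grid_spec()].
#' @param velocity_threshold,min_separation Passed to [flag_blinks()].
#' @return An object of class `quality_report`.
#' @export
grid_quality_report <- function(blocks, grid, velocity_threshold = 200,
                                min_separation = 0.2) {
  med <- fixation_medians(blocks)
  blink <- dplyr::bind_rows(lapply(seq_along(blocks), function(p) {
    s <- blocks[[p]]$samples
    if (sum(s$valid) < 2L) return(NULL)
    b <- flag_blinks(blocks[[p]], velocity_threshold, min_separation)
    if (nrow(b)) b$point <- p
    b
  }))
  structure(
    list(
      scale_ratio_x = scale_ratio(med, grid, "x"),
      scale_ratio_y = scale_ratio(med, grid, "y"),
      precision_ratio_x = precision_ratio(blocks, grid, "x"),
      precision_ratio_y = precision_ratio(blocks, grid, "y"),
      data_loss_pct = data_loss(blocks),
      per_fixation_medians = med,
      blink_intervals = blink
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> scale x/y: %.3f/%.3f  precision x/y: %.3f/%.3f  loss: %.2f%%  blinks: %d\n",
    x$scale_ratio_x, x$scale_ratio_y, x$precision_ratio_x, x$precision_ratio_y,
    x$data_loss_pct, nrow(x$blink_intervals)))
  invisible(x)
}
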