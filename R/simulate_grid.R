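#' Configuration for simulated grid fixation sessions
#'
#' The generative model for one grid session: the participant fixates
#' each stimulus point for `dwell_per_point` seconds while the estimator
#' reports, per axis, `gain * true_angle + offset + N(0, noise_sd^2)`.
#' Gains below 1 emulate the scale under-estimation typical of
#' calibration-free estimators; the default gains sit in the middle of
#' the 0.3-0.7 range such estimators show when the participant fixates
#' with the eyes only.  Blink transients add a sharp excursion of
#' `blink_amplitude` degrees to the vertical channel for
#' `blink_duration` seconds while the sample stays valid (estimators
#' keep reporting through closed eyes); data loss is a separate,
#' independent mechanism controlled by `p_missing`.
#'
#' @param gain_x,gain_y Multiplicative scale factors (> 0); defaults
#'   0.5 and 0.4 (vertical typically worse).
#' @param offset_x,offset_y Additive offsets in degrees; defaults 2, -1
#'   (the estimator's origin is arbitrary).
#' @param noise_sd_x,noise_sd_y Within-fixation noise SD in degrees;
#'   defaults 0.5.
#' @param blink_rate Blink events per minute (default 2).
#' @param blink_amplitude Vertical transient in degrees (default -10,
#'   i.e. a sharp downward excursion when the lids close).
#' @param blink_duration Transient duration in seconds (default 0.15).
#' @param p_missing Per-sample probability of an invalid sample
#'   (default 0).
#' @param rate Sampling rate in Hz (default 60).
#' @param dwell_per_point Fixation duration per stimulus point in
#'   seconds (default 3).
#' @param seed Integer seed; identical seed and config give
#'   bit-identical sessions.
#'
#' @return An object of class `grid_sim_config`.
#' @export
grid_sim_config <- function(gain_x = 0.5, gain_y = 0.4, offset_x = 2,
                            offset_y = -1, noise_sd_x = 0.5, noise_sd_y = 0.5,
                            blink_rate = 2, blink_amplitude = -10,
                            blink_duration = 0.15, p_missing = 0,
                            rate = 60, dwell_per_point = 3, seed = 1L) {
  stopifnot(gain_x > 0, gain_y > 0, noise_sd_x >= 0, noise_sd_y >= 0,
            blink_rate >= 0, blink_duration > 0,
            p_missing >= 0, p_missing <= 1, rate > 0, dwell_per_point > 0)
  structure(as.list(environment()), class = "grid_sim_config")
}

#' Simulate one grid fixation session
#'
#' Generates one gaze recording per stimulus point (row-major
#' presentation order) under the model of [grid_sim_config()], plus the
#' ground truth needed by recovery tests: the true per-point angles and
#' the injected blink intervals.
#'
#' @param grid A [grid_spec()].
#' @param cfg A [grid_sim_config()].
#' @return An object of class `grid_session`: list with `recordings`
#'   (list of 9 [gaze_recording()]s), `truth` (output of
#'   [grid_point_angles()]), `blinks` (tibble `point`, `start`, `end`)
#'   and `cfg`.
#' @export
simulate_grid_session <- function(grid, cfg = grid_sim_config()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(cfg, "grid_sim_config"))
  truth <- grid_point_angles(grid)
  n <- round(cfg$rate * cfg$dwell_per_point)
  t <- (seq_len(n) - 1) / cfg$rate
  withr::with_seed(cfg$seed, {
    recs <- vector("list", nrow(truth))
    blinks <- list()
    for (p in seq_len(nrow(truth))) {
      x <- cfg$gain_x * truth$theta_x[p] + cfg$offset_x +
        rnorm(n, 0, cfg$noise_sd_x)
      y <- cfg$gain_y * truth$theta_y[p] + cfg$offset_y +
        rnorm(n, 0, cfg$noise_sd_y)
      nb <- rpois(1, cfg$blink_rate * cfg$dwell_per_point / 60)
      if (nb > 0) {
        starts <- runif(nb, 0, max(cfg$dwell_per_point - cfg$blink_duration, 0))
        for (b in seq_len(nb)) {
          idx <- t >= starts[b] & t < starts[b] + cfg$blink_duration
          y[idx] <- y[idx] + cfg$blink_amplitude
          blinks[[length(blinks) + 1L]] <-
            tibble::tibble(point = p, start = starts[b],
                           end = starts[b] + cfg$blink_duration)
        }
      }
      valid <- runif(n) >= cfg$p_missing
      recs[[p]] <- gaze_recording(
        t = t, x = ifelse(valid, x, NA_real_), y = ifelse(valid, y, NA_real_),
        valid = valid, nominal_rate = cfg$rate, source = "angle_degrees",
        meta = list(point = p, theta_x = truth$theta_x[p],
                    theta_y = truth$theta_y[p])
      )
    }
    structure(
      list(recordings = recs, truth = truth,
           blinks = if (length(blinks)) dplyr::bind_rows(blinks)
                    else tibble::tibble(point = integer(), start = numeric(),
                                        end = numeric()),
           cfg = cfg),
      class = "grid_session"
    )
  })
}
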