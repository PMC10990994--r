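#' Enumerate the recordings of a grid study design
#'
#' The grid study records each participant twice per condition, giving
#' `n_participants * n_recordings` recordings per condition (18 with
#' the default 9 participants and 2 repetitions).
#'
#' @param n_participants Number of participants (default 9).
#' @param n_recordings Repetitions per participant and condition
#'   (default 2).
#' @param conditions Condition labels (default eyes-only and
#'   head-and-eyes).
#' @return Tibble with columns `participant`, `recording`, `condition`,
#'   one row per recording.
#' @export
enumerate_sessions <- function(n_participants = 9L, n_recordings = 2L,
                               conditions = c("eyes_only", "head_and_eyes")) {
  stopifnot(n_participants >= 1L, n_recordings >= 1L, length(conditions) >= 1L)
  g <- expand.grid(recording = seq_len(n_recordings),
                   participant = seq_len(n_participants),
                   condition = conditions, stringsAsFactors = FALSE)
  tibble::tibble(participant = g$participant, recording = g$recording,
                 condition = g$condition)
}

#' Run the grid data-quality study end to end on simulated sessions
#'
#' Simulates the full grid design — every participant, repetition and
#' condition from [enumerate_sessions()] — and computes the quality
#' report for each recording.  Conditions differ by their base gains
#' and noise (head-and-eyes fixation yields larger, more faithful gaze
#' excursions than eyes-only); individual recordings vary around the
#' condition base with log-normal gain factors (sd
#' `gain_spread_log_sd`) and normal offsets, emulating
#' participant-to-participant and repetition-to-repetition variation.
#'
#' @param condition_cfgs Named list of base [grid_sim_config()]s, one
#'   per condition.  Defaults: eyes-only gains (0.5, 0.4),
#'   head-and-eyes gains (0.9, 0.7).
#' @param grid A [grid_spec()].
#' @param sessions Design table from [enumerate_sessions()]; the
#'   default uses the conditions of `condition_cfgs`.
#' @param gain_spread_log_sd Log-sd of per-recording gain variation
#'   (default 0.15).
#' @param offset_spread_sd SD of per-recording offset variation in
#'   degrees (default 2).
#' @param seed Integer seed; per-recording seeds are derived from it.
#' @return An object of class `exp1_result`: list with `per_recording`
#'   (tibble: design columns plus scale ratios, precision ratios, data
#'   loss, blink count), `summary` (per-condition medians) and
#'   `reports` (list of `quality_report`s).
#' @export
run_experiment1 <- function(condition_cfgs = list(
                              eyes_only = grid_sim_config(gain_x = 0.5,
                                                          gain_y = 0.4),
                              head_and_eyes = grid_sim_config(gain_x = 0.9,
                                                              gain_y = 0.7)),
                            grid = grid_spec(),
                            sessions = enumerate_sessions(
                              conditions = names(condition_cfgs)),
                            gain_spread_log_sd = 0.15,
                            offset_spread_sd = 2,
                            seed = 1L) {
  stopifnot(all(sessions$condition %in% names(condition_cfgs)))
  rec_seed <- function(i) as.integer((as.numeric(seed) * 2003 + i * 6007) %%
                                       .Machine$integer.max)
  rows <- list(); reports <- list()
  for (i in seq_len(nrow(sessions))) {
    base <- condition_cfgs[[sessions$condition[i]]]
    cfg_i <- withr::with_seed(rec_seed(i), {
      gf <- exp(rnorm(2, 0, gain_spread_log_sd))
      of <- rnorm(2, 0, offset_spread_sd)
      grid_sim_config(
        gain_x = base$gain_x * gf[1], gain_y = base$gain_y * gf[2],
        offset_x = base$offset_x + of[1], offset_y = base$offset_y + of[2],
        noise_sd_x = base$noise_sd_x, noise_sd_y = base$noise_sd_y,
        blink_rate = base$blink_rate, blink_amplitude = base$blink_amplitude,
        blink_duration = base$blink_duration, p_missing = base$p_missing,
        rate = base$rate, dwell_per_point = base$dwell_per_point,
        seed = rec_seed(i) + 1L
      )
    })
    sess <- simulate_grid_session(grid, cfg_i)
    rep_i <- grid_quality_report(sess$recordings, grid)
    reports[[i]] <- rep_i
    rows[[i]] <- tibble::tibble(
      participant = sessions$participant[i],
      recording = sessions$recording[i],
      condition = sessions$condition[i],
      scale_ratio_x = rep_i$scale_ratio_x,
      scale_ratio_y = rep_i$scale_ratio_y,
      precision_ratio_x = rep_i$precision_ratio_x,
      precision_ratio_y = rep_i$precision_ratio_y,
      data_loss_pct = rep_i$data_loss_pct,
      n_blinks = nrow(rep_i$blink_intervals)
    )
  }
  per_recording <- dplyr::bind_rows(rows)
  summary <- per_recording |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(
      c("scale_ratio_x", "scale_ratio_y", "precision_ratio_x",
        "precision_ratio_y", "data_loss_pct"), median),
      n_recordings = dplyr::n(), .groups = "drop")
  structure(list(per_recording = per_recording, summary = summary,
                 reports = reports),
            class = "exp1_result")
}

#' Run the infant AOI-agreement study end to end on a simulated cohort
#'
#' For every codable participant of the cohort: build the horizontal
#' gaze histogram, segment it into AOI sections, and either exclude the
#' participant (fewer than two discernible peaks) or derive the
#' estimator-side dwell list (sample assignment plus the
#' `switch_frames` hysteresis rule).  The manual-coding side is the
#' ground-truth dwell list degraded by coder boundary jitter.  Included
#' participants' per-AOI measures from both sides then enter the
#' absolute-agreement comparison.
#'
#' @param cohort An [simulate_infant_cohort()] result.
#' @param switch_frames Hysteresis parameter for estimator dwells
#'   (default 3).
#' @param bin_width,smoothing_bw,min_prominence_frac,density_floor_frac
#'   Segmentation parameters, see [build_histogram()] and
#'   [segment_aois()].
#' @param coder_jitter_sd Manual-coder boundary jitter in seconds
#'   (default 0.05); 0 reproduces the ground truth exactly.
#' @param alpha Passed to [compare_measures()].
#' @return An object of class `exp2_result`: list with
#'   `participant_table` (id, status, peak count), `exclusion_log`
#'   (counts by reason plus included), `measures_est`, `measures_man`
#'   (stacked per-subject [dwell_measures()]), `comparison`
#'   (a [compare_measures()] table over included participants) and
#'   `segmentations`.
#' @export
run_experiment2 <- function(cohort, switch_frames = 3L, bin_width = 1,
                            smoothing_bw = 2, min_prominence_frac = 0.1,
                            density_floor_frac = 0.02,
                            coder_jitter_sd = 0.05, alpha = 0.05) {
  stopifnot(inherits(cohort, "infant_cohort"))
  ptab <- list(); me <- list(); mm <- list(); segs <- list()
  for (p in cohort$participants) {
    status <- "included"; n_peaks <- NA_integer_
    if (p$uncodable) {
      status <- "uncodable"
    } else {
      sess <- p$session
      rec <- sess$recording
      h <- build_histogram(rec$samples$x[rec$samples$valid], bin_width)
      seg <- segment_aois(h, smoothing_bw, min_prominence_frac,
                          density_floor_frac)
      segs[[p$id]] <- seg
      n_peaks <- seg$n_peaks
      if (seg$excluded) {
        status <- "too_few_peaks"
      } else {
        dur <- sess$cfg$duration
        est_dw <- detect_dwells_estimated(assign_samples(rec, seg),
                                          switch_frames = switch_frames,
                                          session_end = dur)
        man <- if (coder_jitter_sd > 0) {
          degrade_manual_coding(sess$truth, coder_jitter_sd,
                                seed = sess$cfg$seed + 7L)
        } else sess$truth
        man_dw <- dwells_from_manual(man)
        e <- dwell_measures(est_dw, dur); e$participant <- p$id
        m <- dwell_measures(man_dw, dur); m$participant <- p$id
        me[[p$id]] <- e; mm[[p$id]] <- m
      }
    }
    ptab[[p$id]] <- tibble::tibble(participant = p$id, status = status,
                                   n_peaks = n_peaks)
  }
  participant_table <- dplyr::bind_rows(ptab)
  counts <- table(factor(participant_table$status,
                         levels = c("uncodable", "too_few_peaks", "included")))
  exclusion_log <- tibble::tibble(reason = names(counts),
                                  n = as.integer(counts))
  measures_est <- dplyr::bind_rows(me)
  measures_man <- dplyr::bind_rows(mm)
  comparison <- if (nrow(measures_est)) {
    compare_measures(measures_est, measures_man, alpha)
  } else NULL
  structure(list(participant_table = participant_table,
                 exclusion_log = exclusion_log,
                 measures_est = measures_est, measures_man = measures_man,
                 comparison = comparison, segmentations = segs),
            class = "exp2_result")
}

#' @export
print.exp2_result <- function(x, ...) {
  cat("<exp2_result>\n")
  el <- x$exclusion_log
  cat("  ", paste(sprintf("%s: %d", el$reason, el$n), collapse = "  "), "\n")
  if (!is.null(x$comparison)) {
    cc <- x$comparison[x$comparison$measure == "relative_total", ]
    cat("  relative total dwell time ICC(A,1):",
        paste(sprintf("%s %.2f", cc$aoi, cc$icc), collapse = "  "), "\n")
  }
  invisible(x)
}
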