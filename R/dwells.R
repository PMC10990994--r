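#' Detect dwells from a labeled sample timeline with hysteresis
#'
#' A dwell starts at the first frame whose label is on an AOI and ends
#' only when at least `switch_frames` consecutive frames carry one
#' different label; the new dwell then starts at the first frame of
#' that run.  Shorter excursions do not break the current dwell — their
#' frames stay inside it — which prevents estimate noise from
#' fragmenting looking episodes.  `"none"` is an ordinary label here:
#' it can break a dwell and forms dwells of its own, so the dwell list
#' always partitions the labeled span.  The rule counts frames, not
#' seconds, matching frame-based coding at the native sampling rate.
#'
#' With `switch_frames = 1` the procedure reduces to run-length
#' encoding of the label sequence.
#'
#' @param labels Tibble with columns `t` and `aoi` (from
#'   [assign_samples()]), or a character vector of labels with times
#'   given in `t`.
#' @param t Sample times, only when `labels` is a bare vector.
#' @param switch_frames Consecutive differing frames needed to end a
#'   dwell (default 3); must be >= 1.
#' @param session_end End time of the last dwell; defaults to the last
#'   timestamp plus the median frame interval.
#' @return Tibble of class `dwell_list` with columns `aoi`, `start`,
#'   `end`, `n_frames`; non-overlapping, time-ordered, every frame in
#'   exactly one dwell.
#' @export
detect_dwells_estimated <- function(labels, t = NULL, switch_frames = 3L,
                                    session_end = NULL) {
  if (is.data.frame(labels)) {
    t <- labels$t
    labels <- labels$aoi
  }
  n <- length(labels)
  stopifnot(n >= 1L, length(t) == n)
  if (switch_frames < 1L) stop("switch_frames must be >= 1", call. = FALSE)
  if (is.null(session_end)) {
    session_end <- if (n > 1L) t[n] + median(diff(t)) else t[1] + 1
  }
  starts <- 1L                     # frame index starting each dwell
  dwell_lab <- labels[1]
  cand_lab <- NA_character_        # label of the current differing run
  cand_start <- NA_integer_
  cand_len <- 0L
  for (i in seq_len(n)[-1]) {
    cur <- dwell_lab[length(dwell_lab)]
    if (labels[i] == cur) {
      cand_len <- 0L; cand_lab <- NA_character_
    } else if (!is.na(cand_lab) && labels[i] == cand_lab) {
      cand_len <- cand_len + 1L
    } else {
      cand_lab <- labels[i]; cand_start <- i; cand_len <- 1L
    }
    if (cand_len >= switch_frames) {
      starts <- c(starts, cand_start)
      dwell_lab <- c(dwell_lab, cand_lab)
      cand_len <- 0L; cand_lab <- NA_character_
    }
  }
  ends_idx <- c(starts[-1] - 1L, n)
  out <- tibble::tibble(
    aoi = dwell_lab,
    start = t[starts],
    end = c(t[starts[-1]], session_end),
    n_frames = ends_idx - starts + 1L
  )
  class(out) <- c("dwell_list", class(out))
  out
}

#' Convert a manual-coding file to a dwell list
#'
#' Manual coding needs no hysteresis: the coder sees the surrounding
#' context and already places dwell boundaries at the first frame on a
#' new AOI, so entries map one-to-one onto dwells.  Frame counts are
#' unknown to the coding file and reported as `NA`.
#'
#' @param file A [manual_dwells()] table.
#' @return Tibble of class `dwell_list` with columns `aoi`, `start`,
#'   `end`, `n_frames`.
#' @export
dwells_from_manual <- function(file) {
  stopifnot(inherits(file, "manual_dwells"))
  out <- tibble::tibble(aoi = file$aoi, start = file$start, end = file$end,
                        n_frames = NA_integer_)
  class(out) <- c("dwell_list", class(out))
  out
}
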