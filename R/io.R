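#' Construct a gaze recording
#'
#' A gaze recording is the canonical in-memory container for one
#' continuous stream of gaze estimates: a sample table plus metadata.
#' All downstream statistics operate on this container regardless of
#' which estimator dialect the data came from.
#'
#' The canonical sign convention is: looks from left to right increase
#' `x`, looks from down to up increase `y`.  For angle-valued sources
#' the units are degrees of gaze angle; for normalized sources the
#' values are dimensionless screen coordinates.
#'
#' @param t Numeric vector of sample times in seconds from recording
#'   start; must be non-negative and strictly increasing.
#' @param x,y Numeric vectors of horizontal/vertical gaze estimates.
#' @param valid Logical vector; `FALSE` marks samples whose gaze
#'   estimate is missing.  Invalid samples are ignored by every
#'   downstream statistic except data loss.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @param source `"angle_degrees"` or `"normalized"`.
#' @param meta Named list of free-form metadata (participant id,
#'   condition, stimulus point index, ...).
#'
#' @return An object of class `gaze_recording`: a list with elements
#'   `samples` (tibble with columns `t`, `x`, `y`, `valid`),
#'   `nominal_rate`, `source` and `meta`.
#' @export
gaze_recording <- function(t, x, y, valid = rep(TRUE, length(t)),
                           nominal_rate, source = c("angle_degrees", "normalized"),
                           meta = list()) {
  source <- match.arg(source)
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(valid) == n)
  if (n == 0L) stop("a gaze recording must contain at least one sample", call. = FALSE)
  if (any(t < 0)) stop("sample times must be non-negative", call. = FALSE)
  if (n > 1L && any(diff(t) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      samples = tibble::tibble(t = as.numeric(t), x = as.numeric(x),
                               y = as.numeric(y), valid = as.logical(valid)),
      nominal_rate = nominal_rate,
      source = source,
      meta = meta
    ),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%s), %.1f%% valid\n",
              nrow(s), x$nominal_rate, x$source, 100 * mean(s$valid)))
  invisible(x)
}

#' Validated table of manually coded dwells
#'
#' Manual coding produces, per recording, an ordered list of dwells:
#' which AOI the infant looked at, from when to when.  Entries must
#' partition the coded span: each dwell ends exactly where the next
#' begins.
#'
#' @param aoi Character vector of AOI labels (see [aoi_labels()]).
#' @param start,end Numeric vectors, seconds; `end > start` per entry.
#'
#' @return A tibble of class `manual_dwells` with columns `aoi`,
#'   `start`, `end`.
#' @export
manual_dwells <- function(aoi, start, end) {
  n <- length(aoi)
  stopifnot(length(start) == n, length(end) == n)
  if (n == 0L) stop("empty manual coding file", call. = FALSE)
  bad <- setdiff(unique(aoi), aoi_labels())
  if (length(bad)) {
    stop("unknown AOI label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    stop(sprintf("dwell %d has end <= start (%g <= %g)", i, end[i], start[i]),
         call. = FALSE)
  }
  if (n > 1L && any(diff(start) <= 0)) {
    i <- which(diff(start) <= 0)[1]
    stop(sprintf("dwells out of order at entries %d/%d", i, i + 1L), call. = FALSE)
  }
  if (n > 1L) {
    gap <- which(abs(end[-n] - start[-1]) > 1e-9)
    if (length(gap)) {
      i <- gap[1]
      stop(sprintf(
        "dwells must be contiguous: entry %d ends at %g but entry %d starts at %g",
        i, end[i], i + 1L, start[i + 1L]), call. = FALSE)
    }
  }
  out <- tibble::tibble(aoi = as.character(aoi), start = as.numeric(start),
                        end = as.numeric(end))
  class(out) <- c("manual_dwells", class(out))
  out
}

#' Read model-based estimator output (labeled CSV dialect)
#'
#' Model-based gaze estimators emit a labeled comma-separated table with
#' one row per video frame, containing gaze-angle columns in degrees and
#' a per-frame success indicator.  In the raw output, looks from left to
#' right run positive-to-negative and looks from top to bottom run
#' negative-to-positive; both axes are therefore sign-flipped at load so
#' the in-memory recording follows the canonical convention (rightward
#' and upward positive).  Only the signs are canonical: the absolute
#' origin of the estimator's coordinate system is not interpreted.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector overriding the default
#'   column names, with any of the names `timestamp`, `success`,
#'   `gaze_angle_x`, `gaze_angle_y`.
#' @param nominal_rate Nominal sampling rate in Hz (metadata; default 60).
#' @param meta Optional metadata list.
#'
#' @return A [gaze_recording()] with `source = "angle_degrees"`.  Rows
#'   whose success indicator is 0 or whose gaze fields are empty or
#'   non-numeric become samples with `valid = FALSE`.
#' @export
read_model_based <- function(path, column_map = NULL, nominal_rate = 60,
                             meta = list()) {
  cols <- c(timestamp = "timestamp", success = "success",
            gaze_angle_x = "gaze_angle_x", gaze_angle_y = "gaze_angle_y")
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  d <- read.csv(path, check.names = FALSE, colClasses = "character",
                strip.white = TRUE)
  missing <- setdiff(unname(cols), names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t <- as.numeric(d[[cols["timestamp"]]])
  if (anyNA(t)) stop("non-numeric timestamps", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("timestamps are not strictly increasing", call. = FALSE)
  }
  raw_x <- suppressWarnings(as.numeric(d[[cols["gaze_angle_x"]]]))
  raw_y <- suppressWarnings(as.numeric(d[[cols["gaze_angle_y"]]]))
  success <- suppressWarnings(as.numeric(d[[cols["success"]]]))
  valid <- !is.na(raw_x) & !is.na(raw_y) & !is.na(success) & success != 0
  gaze_recording(
    t = t,
    x = ifelse(valid, -raw_x, NA_real_),  # raw -> canonical sign flip
    y = ifelse(valid, -raw_y, NA_real_),
    valid = valid,
    nominal_rate = nominal_rate,
    source = "angle_degrees",
    meta = meta
  )
}

#' Read appearance-based estimator output (unlabeled 14-column dialect)
#'
#' Appearance-based estimators emit an unlabeled comma-separated table
#' of 14 columns per frame; two of the columns hold the 2-D gaze
#' estimate in normalized screen coordinates.  Which two is
#' configuration, not convention, so it must be supplied.  Frame times
#' come from a sidecar timestamp file (one timestamp in seconds per
#' line) when available, otherwise they are synthesized from the
#' nominal rate.
#'
#' @param path Path to the unlabeled CSV file.
#' @param column_spec Integer vector of length 2: indices (1-based) of
#'   the horizontal and vertical gaze columns.  Default `c(12, 13)`.
#' @param timestamp_path Optional path to the sidecar timestamp file.
#' @param nominal_rate Nominal sampling rate in Hz (default 30).
#' @param n_columns Expected column count (default 14).
#' @param meta Optional metadata list.
#'
#' @return A [gaze_recording()] with `source = "normalized"`.  Rows with
#'   non-numeric gaze fields become `valid = FALSE` samples.
#' @export
read_appearance_based <- function(path, column_spec = c(12L, 13L),
                                  timestamp_path = NULL, nominal_rate = 30,
                                  n_columns = 14L, meta = list()) {
  if (length(column_spec) != 2L || any(column_spec < 1L) ||
      any(column_spec > n_columns)) {
    stop(sprintf("column_spec must name two columns within 1..%d", n_columns),
         call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != n_columns)) {
    i <- which(nf != n_columns)[1]
    stop(sprintf("row %d has %d columns, expected %d", i, nf[i], n_columns),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", column_spec[1])))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", column_spec[2])))
  n <- length(x)
  if (!is.null(timestamp_path)) {
    t <- as.numeric(readLines(timestamp_path))
    if (length(t) != n) {
      stop(sprintf("timestamp file has %d entries for %d data rows",
                   length(t), n), call. = FALSE)
    }
    t <- t - t[1]
  } else {
    t <- (seq_len(n) - 1) / nominal_rate
  }
  valid <- is.finite(x) & is.finite(y)
  gaze_recording(t = t, x = ifelse(valid, x, NA_real_),
                 y = ifelse(valid, y, NA_real_), valid = valid,
                 nominal_rate = nominal_rate, source = "normalized", meta = meta)
}

#' Read a manual-coding dwell file
#'
#' @param path CSV file with header `aoi,start_s,end_s`: one row per
#'   coded dwell, times in seconds.
#' @return A validated [manual_dwells()] table (contiguity, ordering and
#'   label checks applied).
#' @export
read_manual_coding <- function(path) {
  d <- read.csv(path, check.names = FALSE, strip.white = TRUE)
  need <- c("aoi", "start_s", "end_s")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  manual_dwells(d$aoi, d$start_s, d$end_s)
}

#' Write a gaze recording to its source dialect
#'
#' Writes the recording in the on-disk dialect matching its `source`:
#' angle-valued recordings go to the labeled CSV dialect (with the
#' canonical-to-raw sign flip applied, so that reading the file back
#' reproduces the recording exactly), normalized recordings go to the
#' unlabeled 14-column dialect plus a sidecar timestamp file.  Invalid
#' samples are written with empty (angle dialect) or `NaN` (normalized
#' dialect) gaze fields and survive a round trip.
#'
#' @param rec A [gaze_recording()].
#' @param path Output file path.
#' @param timestamp_path Sidecar timestamp path for the normalized
#'   dialect; default `paste0(path, ".ts")`.
#' @param column_spec Gaze column indices for the normalized dialect
#'   (default `c(12, 13)`); the remaining columns are written as 0.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, timestamp_path = paste0(path, ".ts"),
                            column_spec = c(12L, 13L)) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  if (nrow(s) == 0L) stop("nothing to write: empty recording", call. = FALSE)
  if (rec$source == "angle_degrees") {
    out <- data.frame(
      timestamp = s$t,
      success = as.integer(s$valid),
      gaze_angle_x = ifelse(s$valid, -s$x, NA_real_),
      gaze_angle_y = ifelse(s$valid, -s$y, NA_real_)
    )
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    m <- matrix(0, nrow(s), 14L)
    m[, column_spec[1]] <- ifelse(s$valid, s$x, NaN)
    m[, column_spec[2]] <- ifelse(s$valid, s$y, NaN)
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE),
                                              collapse = ",")), path)
    writeLines(format(s$t, digits = 17, trim = TRUE), timestamp_path)
  }
  invisible(path)
}

#' Write a manual-coding dwell file
#'
#' @param dwells A [manual_dwells()] table.
#' @param path Output CSV path (`aoi,start_s,end_s` with header).
#' @return Invisibly, `path`.
#' @export
write_manual_coding <- function(dwells, path) {
  stopifnot(inherits(dwells, "manual_dwells"))
  out <- data.frame(aoi = dwells$aoi, start_s = dwells$start, end_s = dwells$end)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
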