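#' Histogram of horizontal gaze angles
#'
#' The spatial distribution of horizontal gaze estimates over a whole
#' session is the basis for AOI segmentation: with three horizontally
#' separated AOIs one expects three peaks.  Only the horizontal axis is
#' used because the AOIs are horizontally separated and vertical
#' estimates are typically the less reliable channel.
#'
#' @param x_values Numeric vector of horizontal gaze angles (invalid
#'   samples should already be removed; `NA`s are dropped).
#' @param bin_width Bin width in degrees (default 1); must be positive.
#' @return An object of class `gaze_histogram`: list with `breaks`,
#'   `mids`, `counts`, `bin_width`.  Counts sum to the number of
#'   finite input values.
#' @export
build_histogram <- function(x_values, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  x <- x_values[is.finite(x_values)]
  if (!length(x)) stop("no valid gaze values", call. = FALSE)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  structure(list(breaks = h$breaks, mids = h$mids, counts = h$counts,
                 bin_width = bin_width),
            class = "gaze_histogram")
}

# Gaussian-kernel smoothing of histogram counts, evaluated at the bin
# mids.  Returns a vector the same length as counts.
smooth_counts <- function(mids, counts, bandwidth) {
  if (bandwidth <= 0) return(as.numeric(counts))
  vapply(mids, function(m) {
    w <- exp(-0.5 * ((mids - m) / bandwidth)^2)
    sum(w * counts) / sum(w)
  }, numeric(1))
}

# Local maxima of a numeric vector (plateaus compressed; a plateau is a
# peak when both neighbours are lower), with topographic prominence:
# height above the higher of the two key saddles, where a saddle is the
# minimum on the walk toward the nearest higher terrain (or toward the
# boundary if no higher terrain exists on that side).
find_peaks <- function(d) {
  n <- length(d)
  empty <- tibble::tibble(idx = integer(), height = numeric(),
                          prominence = numeric())
  if (n < 3L) return(empty)
  r <- rle(d)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  peak_idx <- integer(0)
  for (j in seq_len(k)) {
    if (j > 1L && j < k && r$values[j] > r$values[j - 1L] &&
        r$values[j] > r$values[j + 1L]) {
      peak_idx <- c(peak_idx, starts[j])
    }
  }
  if (!length(peak_idx)) return(empty)
  prominence <- vapply(peak_idx, function(p) {
    h <- d[p]
    side_min <- function(ix) {
      m <- h
      for (i in ix) {
        if (d[i] > h) return(m)
        m <- min(m, d[i])
      }
      m
    }
    left_min <- side_min(rev(seq_len(p - 1L)))
    right_min <- side_min(seq(p + 1L, n))
    h - max(left_min, right_min)
  }, numeric(1))
  tibble::tibble(idx = peak_idx, height = d[peak_idx],
                 prominence = prominence)
}

#' Segment the horizontal gaze axis into AOI sections
#'
#' Automates the by-eye division of a session's horizontal gaze
#' histogram into AOI sections.  The histogram counts are smoothed with
#' a Gaussian kernel; local maxima whose topographic prominence reaches
#' `min_prominence_frac` of the global maximum count as discernible
#' peaks.
#'
#' * Three (or more) discernible peaks: the three most prominent,
#'   left to right, are taken as left lamp, parent and right lamp.
#'   Sections run valley to valley, then are trimmed wherever the
#'   smoothed density falls below `density_floor_frac` of its maximum,
#'   so sparse tails between and outside the peaks belong to no
#'   section (a "none" region exists).
#' * Exactly two discernible peaks: the peaks become the two lamps
#'   (infants look mostly at the attractive lamps) and the space
#'   between them is assumed to be the parent section.
#' * Fewer than two discernible peaks: the participant's spatial
#'   structure is not segmentable and the result is flagged
#'   `excluded`; this is a result, not an error.
#'
#' @param histogram A [build_histogram()] result.
#' @param smoothing_bw Gaussian kernel bandwidth in degrees (default 2).
#' @param min_prominence_frac Peak prominence threshold as a fraction
#'   of the global smoothed maximum (default 0.1).
#' @param density_floor_frac Density floor for section trimming, as a
#'   fraction of the smoothed maximum (default 0.02).
#' @return An object of class `aoi_segmentation`: list with `sections`
#'   (tibble `aoi`, `lo`, `hi`; zero rows when excluded), `n_peaks`
#'   (number of discernible peaks), `excluded`, `valleys` (untrimmed
#'   valley positions between the used peaks), `peaks` (positions of
#'   the used peaks) and `density` (tibble `x`, `d`).
#' @export
segment_aois <- function(histogram, smoothing_bw = 2,
                         min_prominence_frac = 0.1,
                         density_floor_frac = 0.02) {
  stopifnot(inherits(histogram, "gaze_histogram"))
  # pad with empty bins so the smoothed density decays to zero outside
  # the observed range; otherwise a mode flush against the data edge
  # never develops the low shoulder that peak prominence and the
  # density floor rely on
  bw_bin <- histogram$bin_width
  pad <- ceiling(3 * smoothing_bw / bw_bin)
  mids <- c(histogram$mids[1] - (pad:1) * bw_bin, histogram$mids,
            histogram$mids[length(histogram$mids)] + (1:pad) * bw_bin)
  counts <- c(rep(0, pad), histogram$counts, rep(0, pad))
  breaks <- c(histogram$breaks[1] - (pad:1) * bw_bin, histogram$breaks,
              histogram$breaks[length(histogram$breaks)] + (1:pad) * bw_bin)
  d <- smooth_counts(mids, counts, smoothing_bw)
  dens <- tibble::tibble(x = mids, d = d)
  pk_all <- find_peaks(d)
  pk_all <- pk_all[pk_all$prominence >= min_prominence_frac * max(d), ,
                   drop = FALSE]
  n_peaks <- nrow(pk_all)
  empty <- tibble::tibble(aoi = character(), lo = numeric(), hi = numeric())
  if (n_peaks < 2L) {
    return(structure(list(sections = empty, n_peaks = n_peaks,
                          excluded = TRUE, valleys = numeric(),
                          peaks = mids[pk_all$idx], density = dens),
                     class = "aoi_segmentation"))
  }
  pk <- if (n_peaks > 3L) pk_all[order(-pk_all$prominence), ][1:3, ] else pk_all
  pk <- pk[order(pk$idx), ]
  used <- pk$idx
  n <- length(d)
  floor_d <- density_floor_frac * max(d)
  # valley (minimum of the smoothed density) between two peak indices
  valley_between <- function(a, b) a + which.min(d[(a + 1L):(b - 1L)])
  # hard growth boundaries for each used peak: the valley toward the
  # nearest neighbouring mode on either side, else the data edge —
  # sections never invade another mode, discernible or not (any local
  # maximum rising at least density_floor_frac above its saddle bounds
  # growth; weaker wiggles are below the floor and stop growth anyway)
  pk_bound <- find_peaks(d)
  pk_bound <- pk_bound[pk_bound$prominence >= floor_d, , drop = FALSE]
  all_idx <- sort(unique(c(pk_bound$idx, used)))
  bounds <- lapply(used, function(u) {
    left_nb <- all_idx[all_idx < u]
    right_nb <- all_idx[all_idx > u]
    c(lo = if (length(left_nb)) valley_between(max(left_nb), u) else 1L,
      hi = if (length(right_nb)) valley_between(u, min(right_nb)) - 1L else n)
  })
  # grow a section outward from a peak until density drops below floor
  # or a hard boundary index is reached; returns x-interval
  trim_section <- function(peak, lo_idx, hi_idx) {
    l <- peak
    while (l > lo_idx && d[l - 1L] >= floor_d) l <- l - 1L
    r <- peak
    while (r < hi_idx && d[r + 1L] >= floor_d) r <- r + 1L
    c(lo = breaks[l], hi = breaks[r + 1L])
  }
  if (nrow(pk) == 3L) {
    s1 <- trim_section(used[1], bounds[[1]]["lo"], bounds[[1]]["hi"])
    s2 <- trim_section(used[2], bounds[[2]]["lo"], bounds[[2]]["hi"])
    s3 <- trim_section(used[3], bounds[[3]]["lo"], bounds[[3]]["hi"])
    sections <- tibble::tibble(
      aoi = c("left_lamp", "parent", "right_lamp"),
      lo = c(s1["lo"], s2["lo"], s3["lo"]),
      hi = c(s1["hi"], s2["hi"], s3["hi"]))
    valleys <- c(mids[valley_between(used[1], used[2])],
                 mids[valley_between(used[2], used[3])])
  } else {
    s1 <- trim_section(used[1], bounds[[1]]["lo"], bounds[[1]]["hi"])
    s3 <- trim_section(used[2], bounds[[2]]["lo"], bounds[[2]]["hi"])
    sections <- tibble::tibble(
      aoi = c("left_lamp", "parent", "right_lamp"),
      lo = c(s1["lo"], s1["hi"], s3["lo"]),
      hi = c(s1["hi"], s3["lo"], s3["hi"]))
    valleys <- mids[valley_between(used[1], used[2])]
  }
  structure(list(sections = sections, n_peaks = n_peaks, excluded = FALSE,
                 valleys = valleys, peaks = mids[used], density = dens),
            class = "aoi_segmentation")
}

#' @export
print.aoi_segmentation <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<aoi_segmentation> EXCLUDED (%d discernible peak(s))\n",
                x$n_peaks))
  } else {
    cat(sprintf("<aoi_segmentation> %d peaks; sections: %s\n", x$n_peaks,
                paste(sprintf("%s [%.1f, %.1f]", x$sections$aoi,
                              x$sections$lo, x$sections$hi),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Assign each gaze sample to an AOI
#'
#' Labels every sample of a recording by the AOI section containing its
#' horizontal gaze estimate.  Samples outside all sections, and invalid
#' samples, are labeled `"none"`.  Section intervals are treated as
#' `[lo, hi)` except the rightmost, which is closed.
#'
#' @param rec A [gaze_recording()].
#' @param seg A non-excluded [aoi_segmentation()].
#' @return Tibble with columns `t` and `aoi` (one row per sample).
#' @export
assign_samples <- function(rec, seg) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(seg, "aoi_segmentation"))
  if (seg$excluded) {
    stop("cannot assign samples with an excluded segmentation", call. = FALSE)
  }
  s <- rec$samples
  lab <- rep("none", nrow(s))
  for (i in seq_len(nrow(seg$sections))) {
    lo <- seg$sections$lo[i]; hi <- seg$sections$hi[i]
    closed <- i == nrow(seg$sections)
    inside <- s$valid & !is.na(s$x) & s$x >= lo &
      (if (closed) s$x <= hi else s$x < hi)
    lab[inside] <- seg$sections$aoi[i]
  }
  tibble::tibble(t = s$t, aoi = lab)
}
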