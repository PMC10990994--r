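#' Dwell-based looking measures for one session
#'
#' Summarises a dwell list into the per-AOI measures used for
#' inter-method comparison: relative total dwell time (summed dwell
#' duration as a fraction of session duration), mean dwell duration in
#' seconds, and dwell count.  An AOI without dwells has relative total
#' 0 but mean duration `NA` — reporting 0 there would fabricate
#' agreement on a quantity that was never observed.
#'
#' @param dwells A `dwell_list` tibble ([detect_dwells_estimated()] or
#'   [dwells_from_manual()]).
#' @param session_duration Session length in seconds; all dwells must
#'   lie within `[0, session_duration]`.
#' @return Tibble with one row per label of [aoi_labels()]: columns
#'   `aoi`, `relative_total`, `mean_duration`, `n_dwells`.  When the
#'   dwell list partitions the session the relative totals sum to 1.
#' @export
dwell_measures <- function(dwells, session_duration) {
  stopifnot(is.data.frame(dwells), session_duration > 0)
  if (nrow(dwells) &&
      (min(dwells$start) < -1e-9 ||
       max(dwells$end) > session_duration + 1e-9)) {
    stop("dwells fall outside [0, session_duration]", call. = FALSE)
  }
  dur <- dwells$end - dwells$start
  out <- lapply(aoi_labels(), function(a) {
    d <- dur[dwells$aoi == a]
    tibble::tibble(
      aoi = a,
      relative_total = sum(d) / session_duration,
      mean_duration = if (length(d)) mean(d) else NA_real_,
      n_dwells = length(d)
    )
  })
  dplyr::bind_rows(out)
}

# Koo-Li reliability label for a single ICC value
koo_li_label <- function(r) {
  if (r < 0.5) "poor"
  else if (r < 0.75) "moderate"
  else if (r < 0.9) "good"
  else "excellent"
}

#' Intraclass correlation ICC(A,1): two-way random, absolute agreement,
#' single measures
#'
#' Quantifies absolute agreement between two measurement methods
#' ("raters") over subjects, from the two-way random-effects ANOVA mean
#' squares (rows = subjects, columns = raters):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' Unlike a Pearson correlation, a systematic offset between the
#' methods lowers the coefficient.  The 95% confidence interval follows
#' the F-based absolute-agreement construction with a Satterthwaite
#' denominator degree of freedom, and the one-sided test of ICC > 0
#' uses `F = MS_R / MS_E` with `df1 = n - 1`,
#' `df2 = (n - 1)(k - 1)`.  The returned interpretation applies the
#' conventional reliability labels (poor < 0.5, moderate < 0.75,
#' good < 0.9, excellent above) to the two CI bounds, the conservative
#' reading recommended for small samples.
#'
#' @param x,y Paired per-subject values from the two methods.  Subject
#'   pairs with a missing value are dropped with a warning; at least 3
#'   complete pairs are required.
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `f_stat`, `df1`, `df2`, `p`, `n`, `k`,
#'   `interpretation` (labels for the CI bounds).
#' @export
icc_a1 <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  if (any(!keep)) {
    warning(sprintf("%d subject(s) dropped pairwise for missing values",
                    sum(!keep)), call. = FALSE)
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x); k <- 2L
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    stop("undefined ICC: zero variance in both raters", call. = FALSE)
  }
  d <- data.frame(v = c(x, y),
                  subject = factor(rep(seq_len(n), 2L)),
                  rater = factor(rep(c("a", "b"), each = n)))
  ms <- suppressWarnings(anova(lm(v ~ subject + rater, data = d))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  tiny <- 1e-12 * max(msr, msc, mse)
  if (mse <= tiny || icc >= 1 - 1e-12) {
    # (essentially) perfect fit: agreement limited only by rounding
    f_stat <- Inf; p <- 0
    ci <- if (msc <= tiny) c(1, 1) else c(NA_real_, 1)
  } else {
    f_stat <- msr / mse
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, df1, v)
    fu <- qf(1 - alpha / 2, v, df1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  }
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2], f_stat = f_stat,
         df1 = df1, df2 = df2, p = p, n = n, k = k, alpha = alpha,
         interpretation = c(low = if (is.na(ci[1])) NA_character_
                                  else koo_li_label(ci[1]),
                            high = koo_li_label(ci[2]))),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  stars <- if (x$p < 0.001) "***" else if (x$p < 0.01) "**"
           else if (x$p < 0.05) "*" else ""
  cat(sprintf(
    "ICC(A,1) = %.2f%s, %d%% CI [%.2f, %.2f] (%s to %s), F(%d, %d) = %.2f, p = %.3g, n = %d\n",
    x$icc, stars, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
    x$interpretation["low"], x$interpretation["high"],
    x$df1, x$df2, x$f_stat, x$p, x$n))
  invisible(x)
}

#' Compare estimator-derived and manually coded looking measures
#'
#' For every AOI and measure (relative total dwell time, mean dwell
#' duration), pairs the per-subject values from the two methods,
#' reports the per-method medians and the absolute-agreement
#' [icc_a1()].  Subjects with an undefined measure on either side
#' (an AOI never dwelt on) are dropped pairwise for that cell, with the
#' dropped count recorded.
#'
#' @param est,man Tibbles of per-subject measures with columns
#'   `participant`, `aoi`, `relative_total`, `mean_duration`,
#'   `n_dwells` (stacked [dwell_measures()] outputs).  Both must cover
#'   the same participant set.
#' @param alpha Passed to [icc_a1()].
#' @return Tibble of class `measure_comparison`: one row per AOI and
#'   measure with medians, `n_pairs`, `n_dropped`, the ICC point
#'   estimate, CI, F, dfs, p and CI-bound interpretation, plus a
#'   list-column `icc_result`.
#' @export
compare_measures <- function(est, man, alpha = 0.05) {
  se <- sort(unique(est$participant)); sm <- sort(unique(man$participant))
  if (!identical(se, sm)) {
    stop("participant sets differ: ",
         paste(c(setdiff(se, sm), setdiff(sm, se)), collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (a in aoi_labels()) {
    for (meas in c("relative_total", "mean_duration")) {
      e <- est[est$aoi == a, c("participant", meas)]
      m <- man[man$aoi == a, c("participant", meas)]
      j <- merge(e, m, by = "participant", suffixes = c("_est", "_man"))
      xv <- j[[paste0(meas, "_est")]]
      yv <- j[[paste0(meas, "_man")]]
      ok <- !is.na(xv) & !is.na(yv)
      res <- if (sum(ok) >= 3L && !(sd(xv[ok]) == 0 && sd(yv[ok]) == 0)) {
        suppressWarnings(icc_a1(xv, yv, alpha))
      } else NULL
      rows[[length(rows) + 1L]] <- tibble::tibble(
        aoi = a, measure = meas,
        median_est = median(xv, na.rm = TRUE),
        median_man = median(yv, na.rm = TRUE),
        n_pairs = sum(ok), n_dropped = sum(!ok),
        icc = if (is.null(res)) NA_real_ else res$icc,
        ci_low = if (is.null(res)) NA_real_ else res$ci_low,
        ci_high = if (is.null(res)) NA_real_ else res$ci_high,
        f_stat = if (is.null(res)) NA_real_ else res$f_stat,
        df1 = if (is.null(res)) NA_integer_ else res$df1,
        df2 = if (is.null(res)) NA_integer_ else res$df2,
        p = if (is.null(res)) NA_real_ else res$p,
        interpretation = if (is.null(res)) NA_character_ else
          paste(res$interpretation, collapse = " to "),
        icc_result = list(res)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("measure_comparison", class(out))
  out
}
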