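test_that("dwell measures do the arithmetic they claim", {
  d <- tibble::tibble(aoi = c("left_lamp", "parent"),
                      start = c(0, 30), end = c(30, 90),
                      n_frames = c(900L, 1800L))
  m <- dwell_measures(d, 90)
  expect_equal(m$relative_total[m$aoi == "left_lamp"], 1 / 3)
  expect_equal(m$relative_total[m$aoi == "parent"], 2 / 3)
  expect_equal(m$mean_duration[m$aoi == "left_lamp"], 30)
  expect_equal(m$mean_duration[m$aoi == "parent"], 60)
  expect_equal(m$n_dwells[m$aoi == "none"], 0L)
  expect_true(is.na(m$mean_duration[m$aoi == "none"]))

  whole <- tibble::tibble(aoi = "left_lamp", start = 0, end = 90,
                          n_frames = 2700L)
  mw <- dwell_measures(whole, 90)
  expect_equal(mw$relative_total, c(1, 0, 0, 0))

  outside <- tibble::tibble(aoi = "parent", start = 80, end = 95,
                            n_frames = 450L)
  expect_error(dwell_measures(outside, 90), "outside")
})

test_that("relative totals sum to one whenever dwells partition the session", {
  for (seed in 1:5) {
    s <- simulate_infant_session(infant_sim_config(seed = seed))
    m <- dwell_measures(dwells_from_manual(s$truth), 90)
    expect_equal(sum(m$relative_total), 1)
  }
})

test_that("icc_a1 reproduces an externally computed reference table", {
  # reference values computed two independent ways (mean-squares
  # arithmetic and a published ICC implementation), agreeing to 1e-15
  x <- c(7.1, 5.4, 8.2, 6.3, 9.0, 4.8)
  y <- c(6.8, 5.9, 8.5, 6.0, 8.7, 5.2)
  r <- icc_a1(x, y)
  expect_equal(r$icc, 0.9726737170842502, tolerance = 1e-10)
  expect_equal(r$ci_low, 0.8237552464579047, tolerance = 1e-8)
  expect_equal(r$ci_high, 0.9961193231847835, tolerance = 1e-8)
  expect_equal(r$f_stat, 61.5033112582785, tolerance = 1e-10)
  expect_equal(r$df1, 5L)
  expect_equal(r$df2, 5L)
  expect_equal(r$p, 0.00017288435089030666, tolerance = 1e-8)
  expect_equal(unname(r$interpretation), c("good", "excellent"))
})

test_that("icc_a1 equals brute-force mean-squares arithmetic on random tables", {
  set.seed(20)
  for (i in 1:25) {
    x <- rnorm(6, 5, 2)
    y <- x + rnorm(6, 0.5, 1)
    expect_equal(icc_a1(x, y)$icc, icc_a1_brute(x, y), tolerance = 1e-10)
  }
})

test_that("perfect agreement gives ICC 1 and offsets are penalized", {
  x <- c(1, 3, 2, 5, 4, 6)
  r <- icc_a1(x, x)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)

  roff <- icc_a1(x, x + 3)
  expect_equal(roff$icc, icc_a1_brute(x, x + 3), tolerance = 1e-12)
  expect_lt(roff$icc, 1)                       # absolute agreement penalty
  expect_equal(cor(x, x + 3), 1)               # which Pearson ignores
  # frozen reference for this exact table (see reference test above)
  expect_equal(icc_a1(c(7.1, 5.4, 8.2, 6.3, 9.0, 4.8),
                      c(7.1, 5.4, 8.2, 6.3, 9.0, 4.8) + 3)$icc,
               0.36797752808988726, tolerance = 1e-10)
})

test_that("icc_a1 is symmetric and jointly affine-invariant", {
  set.seed(21)
  x <- rnorm(10); y <- x + rnorm(10, 0, 0.5)
  expect_equal(icc_a1(x, y)$icc, icc_a1(y, x)$icc, tolerance = 1e-12)
  expect_equal(icc_a1(2 * x + 5, 2 * y + 5)$icc, icc_a1(x, y)$icc,
               tolerance = 1e-12)
  # adding a constant to one rater only strictly decreases agreement
  expect_lt(icc_a1(x, y + 2)$icc, icc_a1(x, y)$icc)
})

test_that("icc_a1 recovers the population ICC of a variance-components model", {
  # subject effect variance 4, residual variance 1 -> ICC(A,1) = 0.8
  set.seed(22)
  n <- 400
  subj <- rnorm(n, 0, 2)
  x <- subj + rnorm(n, 0, 1)
  y <- subj + rnorm(n, 0, 1)
  expect_equal(icc_a1(x, y)$icc, 0.8, tolerance = 0.06)
})

test_that("icc_a1 input contracts", {
  expect_error(icc_a1(1:2, 1:2), "at least 3")
  expect_error(icc_a1(rep(1, 5), rep(2, 5)), "zero variance")
  expect_warning(r <- icc_a1(c(1, 2, 3, 4, NA), c(1.1, 2.2, 2.9, 4.2, 5)),
                 "dropped")
  expect_equal(r$n, 4L)
})

test_that("Koo-Li interpretation maps the CI bounds, not the point estimate", {
  x <- c(7.1, 5.4, 8.2, 6.3, 9.0, 4.8)
  set.seed(23)
  r <- icc_a1(x, x + rnorm(6, 0, 1.5))
  labels <- c("poor", "moderate", "good", "excellent")
  expect_true(all(r$interpretation %in% labels))
  expect_lte(match(r$interpretation["low"], labels),
             match(r$interpretation["high"], labels))
})

test_that("compare_measures pairs subjects and spots mismatches", {
  base <- tibble::tibble(
    participant = rep(sprintf("s%02d", 1:6), each = 4),
    aoi = rep(aoi_labels(), 6),
    relative_total = runif(24),
    mean_duration = runif(24, 1, 3),
    n_dwells = rep(5L, 24))
  cmp <- compare_measures(base, base)
  expect_true(all(cmp$icc[cmp$measure == "relative_total"] == 1))
  expect_equal(cmp$median_est, cmp$median_man)

  other <- base
  other$participant[other$participant == "s06"] <- "s99"
  expect_error(compare_measures(base, other), "s99|s06")
})
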