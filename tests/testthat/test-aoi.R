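test_that("histogram conserves counts and covers the data range", {
  set.seed(1)
  x <- rnorm(500, 0, 10)
  h <- build_histogram(x, 1)
  expect_equal(sum(h$counts), 500)
  expect_lte(h$breaks[1], min(x))
  expect_gte(h$breaks[length(h$breaks)], max(x))

  h1 <- build_histogram(rep(3.2, 50), 1)
  expect_equal(sum(h1$counts > 0), 1L)
  expect_equal(sum(h1$counts), 50)

  expect_error(build_histogram(x, 0), "positive")
  expect_error(build_histogram(NA_real_), "valid")
})

test_that("a well-separated trimodal mixture yields three ordered sections", {
  set.seed(2)
  x <- c(rnorm(800, -20, 2), rnorm(700, 0, 2), rnorm(800, 20, 2))
  seg <- segment_aois(build_histogram(x, 1))
  expect_false(seg$excluded)
  expect_equal(seg$sections$aoi, c("left_lamp", "parent", "right_lamp"))
  # ordered and disjoint
  expect_true(all(diff(as.vector(rbind(seg$sections$lo, seg$sections$hi))) >= 0))
  # each section contains its generating mean
  expect_true(all(seg$sections$lo < c(-20, 0, 20) &
                    seg$sections$hi > c(-20, 0, 20)))
})

test_that("section valleys converge to the analytic mixture-density valleys", {
  # equal-weight mixture of N(-20, 2), N(0, 2), N(20, 2): by symmetry
  # the density valleys sit at -10 and +10
  set.seed(3)
  n <- 30000
  x <- c(rnorm(n, -20, 2), rnorm(n, 0, 2), rnorm(n, 20, 2))
  seg <- segment_aois(build_histogram(x, 1))
  expect_equal(length(seg$valleys), 2L)
  expect_lt(abs(seg$valleys[1] - (-10)), 2)
  expect_lt(abs(seg$valleys[2] - 10), 2)
})

test_that("unimodal data are excluded rather than force-fitted", {
  set.seed(4)
  seg <- segment_aois(build_histogram(rnorm(2000, 0, 5), 1))
  expect_true(seg$excluded)
  expect_lt(seg$n_peaks, 2)
  expect_equal(nrow(seg$sections), 0L)
})

test_that("with two peaks the space between them becomes the parent section", {
  set.seed(5)
  x <- c(rnorm(1000, -20, 2), rnorm(1000, 20, 2))
  seg <- segment_aois(build_histogram(x, 1))
  expect_false(seg$excluded)
  expect_equal(seg$n_peaks, 2L)
  s <- seg$sections
  expect_equal(s$aoi, c("left_lamp", "parent", "right_lamp"))
  expect_equal(s$lo[2], s$hi[1])   # parent fills the gap exactly
  expect_equal(s$hi[2], s$lo[3])
  expect_true(s$lo[2] < 0 && s$hi[2] > 0)
})

test_that("sample assignment respects sections, none and validity", {
  seg <- structure(list(
    sections = tibble::tibble(aoi = c("left_lamp", "parent", "right_lamp"),
                              lo = c(-30, -5, 15), hi = c(-15, 5, 30)),
    n_peaks = 3L, excluded = FALSE, valleys = c(-10, 10),
    peaks = c(-20, 0, 20),
    density = tibble::tibble(x = numeric(), d = numeric())),
    class = "aoi_segmentation")
  rec <- rec_from(x = c(-20, 0, 20, 10, -40, 0), y = rep(0, 6),
                  valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  lab <- assign_samples(rec, seg)
  expect_equal(lab$aoi, c("left_lamp", "parent", "right_lamp",
                          "none",       # in no section
                          "none",       # outside everything
                          "none"))      # invalid sample
  excluded <- structure(list(sections = seg$sections[0, ], n_peaks = 1L,
                             excluded = TRUE, valleys = numeric(),
                             peaks = numeric(),
                             density = seg$density),
                        class = "aoi_segmentation")
  expect_error(assign_samples(rec, excluded), "excluded")
})
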