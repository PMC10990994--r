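lab_tl <- function(labels, rate = 30) {
  tibble::tibble(t = (seq_along(labels) - 1) / rate, aoi = labels)
}

test_that("hysteresis rule on hand-built sequences", {
  # a single uninterrupted dwell
  d1 <- detect_dwells_estimated(lab_tl(rep("parent", 10)), switch_frames = 3)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$n_frames, 10L)

  # a 2-frame excursion cannot break a dwell at switch_frames = 3
  d2 <- detect_dwells_estimated(
    lab_tl(c(rep("parent", 5), rep("none", 2), rep("parent", 5))),
    switch_frames = 3)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$aoi, "parent")
  expect_equal(d2$n_frames, 12L)

  # a 3-frame run does break it, and the new dwell starts at the run's
  # first frame
  lab <- lab_tl(c(rep("parent", 5), rep("left_lamp", 3), rep("parent", 5)))
  d3 <- detect_dwells_estimated(lab, switch_frames = 3)
  expect_equal(d3$aoi, c("parent", "left_lamp", "parent"))
  expect_equal(d3$start[2], lab$t[6])
  expect_equal(d3$n_frames, c(5L, 3L, 5L))
})

test_that("with switch_frames = 1 the rule is exactly run-length encoding", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    labels <- sample(aoi_labels(), n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.2, 0.2))
    t <- (seq_len(n) - 1) / 30
    got <- detect_dwells_estimated(labels, t, switch_frames = 1,
                                   session_end = n / 30)
    want <- rle_dwells(labels, t, n / 30)
    expect_equal(got$aoi, want$aoi)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_frames, want$n_frames)
  }
})

test_that("dwell lists partition the frames and absorb sub-threshold runs", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    labels <- sample(c("parent", "none", "left_lamp"), n, replace = TRUE)
    t <- (seq_len(n) - 1) / 30
    d <- detect_dwells_estimated(labels, t, switch_frames = 3,
                                 session_end = n / 30)
    # partition: frames covered exactly once, in order
    expect_equal(sum(d$n_frames), n)
    expect_true(all(diff(d$start) > 0))
    expect_equal(d$end[-nrow(d)], d$start[-1])
    # no adjacent dwells share a label
    if (nrow(d) > 1) expect_true(all(d$aoi[-1] != d$aoi[-nrow(d)]))
    # every dwell after the first begins with >= 3 frames of its label
    starts_idx <- round(d$start * 30) + 1
    for (j in seq_len(nrow(d))[-1]) {
      run <- labels[starts_idx[j]:min(starts_idx[j] + 2, n)]
      expect_true(all(run == d$aoi[j]))
    }
  }
})

test_that("manual dwells convert one-to-one with boundaries intact", {
  md <- manual_dwells(c("left_lamp", "parent", "none"), c(0, 5, 7), c(5, 7, 9))
  d <- dwells_from_manual(md)
  expect_equal(nrow(d), 3L)
  expect_equal(d$start, md$start)
  expect_equal(d$end, md$end)
  expect_equal(sum(d$end - d$start), 9)
})

test_that("configuration errors are rejected", {
  expect_error(detect_dwells_estimated(lab_tl(rep("parent", 5)),
                                       switch_frames = 0), ">= 1")
})
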