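grid <- grid_spec()

noise_free_session <- function(gain_x = 1, gain_y = 1, offset_x = 0,
                               offset_y = 0, seed = 1) {
  simulate_grid_session(grid, grid_sim_config(
    gain_x = gain_x, gain_y = gain_y, offset_x = offset_x, offset_y = offset_y,
    noise_sd_x = 0, noise_sd_y = 0, blink_rate = 0, seed = seed))
}

test_that("fixation medians are robust to outliers and flag empty blocks", {
  b <- rec_from(x = c(1, 2, 100), y = c(0, 0, 0))
  med <- fixation_medians(list(b))
  expect_equal(med$median_x, 2)

  empty <- rec_from(x = c(0, 0), y = c(0, 0), valid = c(FALSE, FALSE))
  expect_warning(med2 <- fixation_medians(list(b, empty)), "without valid")
  expect_true(is.na(med2$median_x[2]))
})

test_that("scale ratio recovers gain exactly and ignores offsets", {
  for (g in c(0.3, 1, 1.4)) {
    med <- fixation_medians(noise_free_session(gain_x = g, gain_y = g)$recordings)
    expect_equal(scale_ratio(med, grid, "x"), g)
    expect_equal(scale_ratio(med, grid, "y"), g)
  }
  med0 <- fixation_medians(noise_free_session(gain_x = 0.6)$recordings)
  medo <- fixation_medians(noise_free_session(gain_x = 0.6, offset_x = 25,
                                              offset_y = -13)$recordings)
  expect_equal(scale_ratio(medo, grid, "x"), scale_ratio(med0, grid, "x"))
  expect_equal(scale_ratio(medo, grid, "y"), scale_ratio(med0, grid, "y"))
})

test_that("precision ratio is zero without noise and invariant to joint rescaling", {
  blocks <- noise_free_session()$recordings
  expect_equal(precision_ratio(blocks, grid, "x"), 0)

  noisy <- simulate_grid_session(grid, grid_sim_config(
    noise_sd_x = 0.8, noise_sd_y = 0.8, blink_rate = 0, seed = 3))$recordings
  r1 <- precision_ratio(noisy, grid, "x")
  doubled <- lapply(noisy, function(b) {
    s <- b$samples
    gaze_recording(s$t, 2 * s$x, 2 * s$y, s$valid, b$nominal_rate, b$source)
  })
  expect_equal(precision_ratio(doubled, grid, "x"), r1)
  expect_gt(r1, 0)
})

test_that("data loss equals a direct brute-force count", {
  set.seed(9)
  valid <- runif(180) > 0.3
  rec <- rec_from(x = rnorm(180), y = rnorm(180), valid = valid)
  expect_equal(data_loss(rec), 100 * sum(!valid) / 180)
  all_valid <- rec_from(x = rnorm(10), y = rnorm(10))
  expect_equal(data_loss(all_valid), 0)
  half <- rec_from(x = rnorm(180), y = rnorm(180),
                   valid = rep(c(TRUE, FALSE), 90))
  expect_equal(data_loss(half), 50)
})

test_that("blink flagging recovers injected transients and obeys its limits", {
  const <- rec_from(x = rnorm(100), y = rep(1, 100))
  expect_equal(nrow(flag_blinks(const)), 0)

  cfg <- grid_sim_config(blink_rate = 20, noise_sd_y = 0.3, seed = 13)
  s <- simulate_grid_session(grid, cfg)
  pts <- unique(s$blinks$point)
  for (p in pts) {
    found <- flag_blinks(s$recordings[[p]])
    injected <- s$blinks[s$blinks$point == p, ]
    # every injected blink overlaps at least one flagged interval
    for (i in seq_len(nrow(injected))) {
      overlaps <- found$start <= injected$end[i] + 0.05 &
        found$end >= injected$start[i] - 0.05
      expect_true(any(overlaps))
    }
  }
  expect_equal(nrow(flag_blinks(s$recordings[[pts[1]]],
                                velocity_threshold = Inf)), 0)
  expect_error(flag_blinks(const, velocity_threshold = 0), "positive")
})

test_that("quality report bundles consistent statistics", {
  s <- simulate_grid_session(grid, grid_sim_config(
    gain_x = 0.5, gain_y = 0.4, noise_sd_x = 0, noise_sd_y = 0,
    blink_rate = 0, p_missing = 0))
  qr <- grid_quality_report(s$recordings, grid)
  expect_equal(qr$scale_ratio_x, 0.5)
  expect_equal(qr$scale_ratio_y, 0.4)
  expect_equal(qr$precision_ratio_x, 0)
  expect_equal(qr$data_loss_pct, 0)
})
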