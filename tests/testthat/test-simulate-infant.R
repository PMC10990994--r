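test_that("identical seed gives identical sessions, different seed differs", {
  cfg <- infant_sim_config(seed = 12)
  s1 <- simulate_infant_session(cfg)
  s2 <- simulate_infant_session(cfg)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_infant_session(infant_sim_config(seed = 13))
  expect_false(identical(s1$recording$samples, s3$recording$samples))
})

test_that("ground-truth coding partitions the session", {
  s <- simulate_infant_session(infant_sim_config(seed = 2))
  tr <- s$truth
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[nrow(tr)], 90)
  expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  m <- dwell_measures(dwells_from_manual(tr), 90)
  expect_equal(sum(m$relative_total), 1)
  # no self-transitions in the coded sequence
  expect_true(all(tr$aoi[-1] != tr$aoi[-nrow(tr)]))
})

test_that("noise-free sessions put AOI samples exactly on the AOI means", {
  cfg <- infant_sim_config(noise_sd = 0, glitch_rate = 0,
                           timestamp_jitter_sd = 0, seed = 4)
  s <- simulate_infant_session(cfg)
  x <- s$recording$samples$x
  for (a in c("left_lamp", "parent", "right_lamp")) {
    idx <- s$frame_states == a
    if (any(idx)) expect_true(all(x[idx] == cfg$aoi_means[[a]]))
  }
  # "none" samples stay inside the off-scene bands
  idx <- s$frame_states == "none"
  expect_true(all(abs(abs(x[idx]) - 45) <= 2 * cfg$none_spread + 1e-9))
})

test_that("interior dwell durations follow the truncated log-normal model", {
  mu <- log(1.8); sig <- 0.6; m <- 0.3
  durs <- unlist(lapply(1:30, function(i) {
    s <- simulate_infant_session(infant_sim_config(
      glitch_rate = 0, seed = 100 + i))
    d <- s$truth$end - s$truth$start
    d[-length(d)]  # final dwell is censored by the session end
  }))
  # E[D | D >= m] for a log-normal
  expected <- exp(mu + sig^2 / 2) *
    pnorm((mu + sig^2 - log(m)) / sig) / pnorm((mu - log(m)) / sig)
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - expected), 4 * se)
})

test_that("horizontal gaze mean matches the time-weighted mixture mean", {
  # symmetric design: means at -20/0/+20 with symmetric weights and
  # symmetric none bands have mixture mean 0
  means <- unlist(lapply(1:25, function(i) {
    s <- simulate_infant_session(infant_sim_config(glitch_rate = 0,
                                                   seed = 300 + i))
    mean(s$recording$samples$x)
  }))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0), 4 * se + 0.5)
})

test_that("coder degradation preserves labels, contiguity and endpoints", {
  s <- simulate_infant_session(infant_sim_config(seed = 6))
  tr <- s$truth
  expect_identical(degrade_manual_coding(tr, 0), tr)

  deg <- degrade_manual_coding(tr, 0.05, seed = 9)
  expect_equal(deg$aoi, tr$aoi)
  expect_equal(deg$start[1], tr$start[1])
  expect_equal(deg$end[nrow(deg)], tr$end[nrow(tr)])
  expect_equal(deg$start[-1], deg$end[-nrow(deg)])
  expect_true(all(deg$end > deg$start))

  single <- manual_dwells("parent", 0, 90)
  expect_identical(degrade_manual_coding(single, 1, seed = 2), single)
})

test_that("small coder jitter moves relative totals only by its own order", {
  s <- simulate_infant_session(infant_sim_config(seed = 8))
  tr <- s$truth
  jit <- 0.05
  m0 <- dwell_measures(dwells_from_manual(tr), 90)
  m1 <- dwell_measures(dwells_from_manual(
    degrade_manual_coding(tr, jit, seed = 3)), 90)
  shift <- abs(m1$relative_total - m0$relative_total)
  # each boundary moves O(jit); ~n_dwells boundaries share the error
  bound <- jit * nrow(tr) / 90
  expect_true(all(shift <= bound))
})

test_that("cohort generation accounts for every participant exactly once", {
  coh <- simulate_infant_cohort(n = 12, n_uncodable = 3, n_unimodal = 2,
                                seed = 5)
  expect_length(coh$participants, 12)
  flags <- vapply(coh$participants, function(p) {
    c(p$uncodable, p$unimodal)
  }, logical(2))
  expect_equal(sum(flags[1, ]), 3)
  expect_equal(sum(flags[2, ]), 2)
  expect_false(any(flags[1, ] & flags[2, ]))
  # deterministic in the cohort seed
  coh2 <- simulate_infant_cohort(n = 12, n_uncodable = 3, n_unimodal = 2,
                                 seed = 5)
  expect_identical(coh$participants[[7]]$session$recording$samples,
                   coh2$participants[[7]]$session$recording$samples)
})
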