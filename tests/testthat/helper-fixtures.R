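# Small builders shared across the suite.

# A recording straight from vectors at a fixed rate.
rec_from <- function(x, y = rep(0, length(x)), rate = 60,
                     valid = rep(TRUE, length(x)),
                     source = "angle_degrees") {
  gaze_recording(t = (seq_along(x) - 1) / rate, x = x, y = y, valid = valid,
                 nominal_rate = rate, source = source)
}

# Write a model-based dialect CSV from raw (unflipped) values.
write_model_csv <- function(path, t, raw_x, raw_y, success = rep(1, length(t))) {
  write.csv(data.frame(timestamp = t, success = success,
                       gaze_angle_x = raw_x, gaze_angle_y = raw_y),
            path, row.names = FALSE, quote = FALSE, na = "")
}

# Brute-force ICC(A,1) from first principles: direct two-way
# mean-squares arithmetic, no model fitting.
icc_a1_brute <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  mse <- sum((m - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + gm)^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Run-length encoding of a label sequence as a dwell table (the
# switch_frames = 1 oracle).
rle_dwells <- function(labels, t, session_end) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts_idx <- ends - r$lengths + 1L
  data.frame(aoi = r$values, start = t[starts_idx],
             end = c(t[starts_idx[-1]], session_end),
             n_frames = r$lengths)
}
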