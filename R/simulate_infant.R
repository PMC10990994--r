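#' Configuration for simulated infant free-looking sessions
#'
#' The generative model for a 90-second infant session in a sparse
#' scene with three horizontally separated areas of interest (a lamp on
#' each side of the parent).  The infant's gaze alternates among the
#' three AOIs and a residual "none" state (looking away from the
#' scene); the next state is drawn from `transition_weights` with no
#' self-transitions, and state durations are log-normal truncated below
#' at `min_dwell`.  During a dwell on an AOI, horizontal gaze estimates
#' are `N(aoi_means[a], noise_sd^2)`; during "none" they come from two
#' flat off-scene bands centred at `none_centers` (far off to either
#' side, past the lamps) with half-width `2 * none_spread`.  The bands
#' have bounded support, so with the default geometry "none" looking
#' never lands inside an AOI section: in the noise-free limit the
#' segmentation pipeline recovers the ground-truth dwell list exactly.
#'
#' Independent of the looking states, brief estimate transients
#' ("glitches", e.g. blinks dragging the estimate off-scene for a few
#' frames) send the horizontal estimate into the none region; the
#' ground-truth coding ignores them, because a human coder watching the
#' video codes through blinks.  They are what makes estimator-side
#' dwells break where manual coding does not.
#'
#' State boundaries are quantised to the frame grid: ground truth is
#' coded per frame, exactly as a human coder stepping through video
#' frames would produce it.
#'
#' @param aoi_means Named numeric, horizontal gaze angle in degrees per
#'   AOI; must be strictly ordered left_lamp < parent < right_lamp.
#'   Default `c(left_lamp = -20, parent = 0, right_lamp = 20)`.
#' @param noise_sd Within-dwell horizontal noise SD in degrees
#'   (default 2).
#' @param none_centers Centres of the two "none" lobes in degrees
#'   (default `c(-45, 45)`).
#' @param none_spread Scale of each "none" band in degrees (default 8;
#'   band half-width is twice this).
#' @param transition_weights Named positive weights over
#'   `left_lamp, parent, right_lamp, none` for the next-state draw
#'   (self-transitions excluded, remaining weights renormalised).
#'   Default uniform.
#' @param dwell_log_mean,dwell_log_sd Log-scale parameters of the
#'   log-normal dwell-duration distribution; defaults `log(1.8)` and
#'   0.6 (median dwell 1.8 s).
#' @param min_dwell Lower truncation of dwell durations in seconds
#'   (default 0.3, i.e. 9 frames at 30 Hz).
#' @param duration Session length in seconds (default 90).
#' @param rate Sampling rate in Hz (default 30).
#' @param timestamp_jitter_sd SD of per-frame timestamp jitter in
#'   seconds (default 0.002; webcams do not tick perfectly).
#' @param glitch_rate Estimate transients per minute (default 6).
#' @param glitch_duration Transient length in seconds (default 0.12,
#'   i.e. 3-4 frames at 30 Hz).
#' @param noise_sd_y Vertical noise SD in degrees (default 4; the
#'   vertical channel is carried along but unused by the horizontal-AOI
#'   analysis).
#' @param seed Integer seed.
#'
#' @return An object of class `infant_sim_config`.
#' @export
infant_sim_config <- function(aoi_means = c(left_lamp = -20, parent = 0,
                                            right_lamp = 20),
                              noise_sd = 2, none_centers = c(-45, 45),
                              none_spread = 8,
                              transition_weights = c(left_lamp = 1, parent = 1,
                                                     right_lamp = 1, none = 1),
                              dwell_log_mean = log(1.8), dwell_log_sd = 0.6,
                              min_dwell = 0.3, duration = 90, rate = 30,
                              timestamp_jitter_sd = 0.002,
                              glitch_rate = 6, glitch_duration = 0.12,
                              noise_sd_y = 4, seed = 1L) {
  stopifnot(duration > 0, rate > 0, noise_sd >= 0, none_spread >= 0,
            min_dwell > 0, glitch_rate >= 0, glitch_duration > 0,
            timestamp_jitter_sd >= 0)
  need <- c("left_lamp", "parent", "right_lamp")
  stopifnot(all(need %in% names(aoi_means)))
  m <- aoi_means[need]
  if (!(m[1] < m[2] && m[2] < m[3])) {
    stop("aoi_means must satisfy left_lamp < parent < right_lamp",
         call. = FALSE)
  }
  stopifnot(all(aoi_labels() %in% names(transition_weights)),
            all(transition_weights > 0))
  structure(as.list(environment())[names(formals(infant_sim_config))],
            class = "infant_sim_config")
}

# Draw an alternating state sequence with truncated log-normal
# durations until `duration` is covered; returns state labels and
# start times.  A trailing partial dwell shorter than min_dwell is
# absorbed into its predecessor.
draw_dwell_sequence <- function(cfg) {
  w <- cfg$transition_weights[aoi_labels()]
  draw_dur <- function() {
    repeat {
      d <- rlnorm(1, cfg$dwell_log_mean, cfg$dwell_log_sd)
      if (d >= cfg$min_dwell) return(d)
    }
  }
  states <- character(0); starts <- numeric(0)
  cur <- sample(aoi_labels(), 1, prob = w / sum(w))
  t0 <- 0
  while (t0 < cfg$duration) {
    states <- c(states, cur); starts <- c(starts, t0)
    t0 <- t0 + draw_dur()
    nxt <- setdiff(aoi_labels(), cur)
    wn <- w[nxt]
    cur <- sample(nxt, 1, prob = wn / sum(wn))
  }
  if (length(states) > 1L &&
      cfg$duration - starts[length(starts)] < cfg$min_dwell) {
    states <- states[-length(states)]
    starts <- starts[-length(starts)]
  }
  list(states = states, starts = starts)
}

#' Simulate one infant free-looking session
#'
#' Generates the gaze recording and its ground truth under the model of
#' [infant_sim_config()].  Ground truth is the frame-quantised manual
#' coding of the underlying state sequence: dwell boundaries are the
#' timestamps of first frames, the final dwell ends at the session
#' duration, and glitches are invisible to it.
#'
#' @param cfg An [infant_sim_config()].
#' @return An object of class `infant_session`: list with `recording`
#'   (a [gaze_recording()]), `truth` (a [manual_dwells()] partitioning
#'   `[0, duration]`), `frame_states` (character vector of per-frame
#'   ground-truth states), `glitches` (tibble `start`, `end`) and `cfg`.
#' @export
simulate_infant_session <- function(cfg = infant_sim_config()) {
  stopifnot(inherits(cfg, "infant_sim_config"))
  n <- round(cfg$duration * cfg$rate)
  withr::with_seed(cfg$seed, {
    # timestamps: nominal frame grid plus jitter, kept strictly
    # increasing and inside [0, duration)
    t <- (seq_len(n) - 1) / cfg$rate
    if (cfg$timestamp_jitter_sd > 0 && n > 1L) {
      t[-1] <- t[-1] + rnorm(n - 1L, 0, cfg$timestamp_jitter_sd)
      t <- pmin(pmax(t, 0), cfg$duration - 1e-6)
      t <- cummax(t) + (seq_len(n) - 1) * 1e-9  # break ties, keep order
    }
    seqn <- draw_dwell_sequence(cfg)
    frame_states <- seqn$states[findInterval(t, seqn$starts)]

    x <- numeric(n)
    for (a in c("left_lamp", "parent", "right_lamp")) {
      idx <- frame_states == a
      x[idx] <- rnorm(sum(idx), cfg$aoi_means[[a]], cfg$noise_sd)
    }
    idx <- frame_states == "none"
    if (any(idx)) {
      lobe <- sample(cfg$none_centers, sum(idx), replace = TRUE)
      x[idx] <- runif(sum(idx), lobe - 2 * cfg$none_spread,
                      lobe + 2 * cfg$none_spread)
    }
    y <- rnorm(n, 0, cfg$noise_sd_y)

    ng <- rpois(1, cfg$glitch_rate * cfg$duration / 60)
    glitches <- tibble::tibble(start = numeric(), end = numeric())
    if (ng > 0) {
      gs <- sort(runif(ng, 0, cfg$duration - cfg$glitch_duration))
      for (g in gs) {
        idx <- t >= g & t < g + cfg$glitch_duration
        if (any(idx)) {
          ctr <- sample(cfg$none_centers, 1)
          x[idx] <- runif(sum(idx), ctr - 2 * cfg$none_spread,
                          ctr + 2 * cfg$none_spread)
        }
      }
      glitches <- tibble::tibble(start = gs, end = gs + cfg$glitch_duration)
    }

    # frame-quantised ground-truth coding
    runs <- rle(frame_states)
    first_idx <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
    starts <- t[first_idx]
    starts[1] <- 0
    ends <- c(starts[-1], cfg$duration)
    truth <- manual_dwells(runs$values, starts, ends)

    rec <- gaze_recording(t = t, x = x, y = y, nominal_rate = cfg$rate,
                          source = "angle_degrees",
                          meta = list(condition = "infant"))
    structure(list(recording = rec, truth = truth,
                   frame_states = frame_states, glitches = glitches,
                   cfg = cfg),
              class = "infant_session")
  })
}

#' Perturb manual-coding boundaries to emulate coder uncertainty
#'
#' Human coders place dwell boundaries with some temporal uncertainty.
#' This jitters every interior boundary by `N(0, boundary_jitter_sd^2)`
#' while preserving label order and contiguity; the outer boundaries
#' (session start and end) never move.  A perturbation that would make
#' a dwell non-positive is clamped just past the previous boundary,
#' with a warning.
#'
#' @param truth A [manual_dwells()] table.
#' @param boundary_jitter_sd Jitter SD in seconds.
#' @param seed Integer seed.
#' @return A [manual_dwells()] table with the same labels.
#' @export
degrade_manual_coding <- function(truth, boundary_jitter_sd, seed = 1L) {
  stopifnot(inherits(truth, "manual_dwells"), boundary_jitter_sd >= 0)
  n <- nrow(truth)
  if (n == 1L || boundary_jitter_sd == 0) return(truth)
  withr::with_seed(seed, {
    b <- c(truth$start[1], truth$start[-1], truth$end[n])  # n+1 boundaries
    inner <- 2:n
    b[inner] <- b[inner] + rnorm(n - 1L, 0, boundary_jitter_sd)
    clamped <- FALSE
    for (i in inner) {
      if (b[i] <= b[i - 1]) { b[i] <- b[i - 1] + 1e-3; clamped <- TRUE }
    }
    if (b[n] >= b[n + 1]) { b[n] <- b[n + 1] - 1e-3; clamped <- TRUE }
    for (i in rev(inner)) {
      if (b[i] >= b[i + 1]) { b[i] <- b[i + 1] - 1e-3; clamped <- TRUE }
    }
    if (clamped) {
      warning("boundary jitter clamped to preserve positive dwell durations",
              call. = FALSE)
    }
    manual_dwells(truth$aoi, b[-(n + 1L)], b[-1L])
  })
}

#' Simulate a cohort of infant sessions with between-participant variation
#'
#' Builds `n` participants around a base configuration, drawing
#' per-participant looking preferences (Dirichlet-perturbed transition
#' weights), dwell-duration level (`dwell_log_mean` shifted by a normal
#' participant effect), AOI positions (small normal shifts of the
#' means) and noise level (log-normal factor), so that looking measures
#' have genuine between-participant variance — the variance against
#' which inter-method agreement (ICC) is judged.
#'
#' Two kinds of degraded participants can be injected, mirroring the
#' exclusion pathway of a real infant study: `n_uncodable` participants
#' whose video could not be manually coded at all (flagged, no further
#' use), and `n_unimodal` participants whose gaze estimates lack
#' spatial separation (collapsed AOI means, inflated noise, little
#' looking away), which downstream segmentation excludes for having
#' fewer than two discernible peaks.  Degraded participants are the
#' first `n_uncodable + n_unimodal` indices; ordering carries no
#' information because every participant gets an independently derived
#' seed.
#'
#' @param n Number of participants (default 44).
#' @param n_uncodable Participants impossible to code manually
#'   (default 14).
#' @param n_unimodal Participants with collapsed spatial structure
#'   (default 5).
#' @param base_cfg Base [infant_sim_config()]; per-participant configs
#'   are derived from it.
#' @param weight_concentration Dirichlet concentration for
#'   per-participant transition weights (default 8; larger = more
#'   homogeneous cohort, `Inf` = identical weights for everyone).
#' @param log_mean_sd SD of the participant effect on `dwell_log_mean`
#'   (default 0.3).
#' @param mean_shift_sd SD of per-participant AOI-mean shifts in
#'   degrees (default 1.5).
#' @param noise_factor_sd SD of the log noise factor (default 0.2).
#' @param seed Integer cohort seed; per-participant seeds are derived
#'   from it.
#' @return An object of class `infant_cohort`: list with `participants`
#'   (list of per-participant lists: `id`, `uncodable`, `unimodal`,
#'   `session`) and the generating arguments.
#' @export
simulate_infant_cohort <- function(n = 44L, n_uncodable = 14L, n_unimodal = 5L,
                                   base_cfg = infant_sim_config(),
                                   weight_concentration = 8,
                                   log_mean_sd = 0.3, mean_shift_sd = 1.5,
                                   noise_factor_sd = 0.2, seed = 1L) {
  stopifnot(n >= n_uncodable + n_unimodal)
  part_seed <- function(i) as.integer((as.numeric(seed) * 1009 + i * 7919) %%
                                        .Machine$integer.max)
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    uncodable <- i <= n_uncodable
    unimodal <- !uncodable && i <= n_uncodable + n_unimodal
    cfg_i <- withr::with_seed(part_seed(i), {
      w <- base_cfg$transition_weights[aoi_labels()]
      w_i <- if (is.finite(weight_concentration)) {
        g <- rgamma(4, shape = weight_concentration * w / sum(w) * 4)
        stats::setNames(g / sum(g), aoi_labels())
      } else {
        stats::setNames(w / sum(w), aoi_labels())  # homogeneous cohort
      }
      shifts <- rnorm(3, 0, mean_shift_sd)
      m_i <- base_cfg$aoi_means[c("left_lamp", "parent", "right_lamp")] + shifts
      m_i <- stats::setNames(sort(m_i),
                             c("left_lamp", "parent", "right_lamp"))
      if (unimodal) {
        # estimates collapsed: AOIs spatially indistinguishable, gaze
        # rarely coded as away
        m_i <- c(left_lamp = -1.5, parent = 0, right_lamp = 1.5)
        noise_i <- 6
        w_i <- c(left_lamp = 0.3, parent = 0.35, right_lamp = 0.3,
                 none = 0.05)
      } else {
        noise_i <- base_cfg$noise_sd * exp(rnorm(1, 0, noise_factor_sd))
      }
      infant_sim_config(
        aoi_means = m_i, noise_sd = noise_i,
        none_centers = base_cfg$none_centers,
        none_spread = base_cfg$none_spread,
        transition_weights = w_i,
        dwell_log_mean = base_cfg$dwell_log_mean + rnorm(1, 0, log_mean_sd),
        dwell_log_sd = base_cfg$dwell_log_sd,
        min_dwell = base_cfg$min_dwell, duration = base_cfg$duration,
        rate = base_cfg$rate,
        timestamp_jitter_sd = base_cfg$timestamp_jitter_sd,
        glitch_rate = base_cfg$glitch_rate,
        glitch_duration = base_cfg$glitch_duration,
        noise_sd_y = base_cfg$noise_sd_y,
        seed = part_seed(i) + 1L
      )
    })
    participants[[i]] <- list(id = sprintf("p%02d", i), uncodable = uncodable,
                              unimodal = unimodal,
                              session = simulate_infant_session(cfg_i))
  }
  structure(list(participants = participants, n = n,
                 n_uncodable = n_uncodable, n_unimodal = n_unimodal,
                 seed = seed),
            class = "infant_cohort")
}
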