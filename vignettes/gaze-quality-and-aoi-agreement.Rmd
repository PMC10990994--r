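---
title: "Evaluating calibration-free gaze estimates: quality statistics, AOI dwells, and agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating calibration-free gaze estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeqc)
```

`gazeqc` evaluates computer-vision gaze estimators that run without
calibration. Such estimators report a gaze signal whose coordinate
system is only partly known: the sign conventions can be determined,
the absolute origin often cannot, and appearance-based estimators
report normalized coordinates on an assumed screen of unknown physical
placement. Every statistic in the package is therefore built to be
meaningful without an absolute origin: ratios of separations,
within-to-between spreads, proportions, and agreement coefficients.

This vignette explains the models behind each stage, the parameters
that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## 1. Canonical data model

A `gaze_recording` holds timestamped samples `(t, x, y, valid)` in one
of two source units (`angle_degrees` or `normalized`), in a canonical
sign convention: looks from left to right increase `x`, looks from
down to up increase `y`. Model-based estimator files use the opposite
sign on both axes, so the reader flips them at load; the flip is an
involution, so writing and re-reading a recording is the identity.
Because the estimators' absolute origin could not be determined, the
canonicalization concerns signs only — no statistic in the package
interprets absolute coordinates.

A sample is *invalid* when the estimator's per-frame success indicator
fails or a gaze field is empty or non-numeric. Invalid samples are
the unit of data loss and are treated as absent by every other
statistic; readers never silently drop rows.

The appearance-based dialect is an unlabeled 14-column table; which
two columns hold the gaze estimate is configuration (`column_spec`,
default columns 12–13), not convention, because the columns carry no
labels. Frame times come from a sidecar timestamp file when present,
else from the nominal rate.

## 2. Grid sessions and their quality statistics

### Geometry

A grid session shows `n_rows × n_cols` points (default 3 × 3, 18.6 cm
horizontal and 11.6 cm vertical spacing, viewed from 95 cm). The
angular separation per axis is a single arctangent,
`atan(spacing / distance)`: 11.08° horizontal, 6.96° vertical by
default. Eccentricity-dependent per-pair angles are deliberately not
modeled — with symmetric, centered grids the adjacent separations are
equal anyway, and a single value per axis keeps the scale ratio's
denominator unambiguous.

### Scale ratio (accuracy of scale)

Per fixation block the median of the valid samples is taken
(medians, not means, so single outliers and blink transients do not
move the fixation location). The scale ratio on an axis is the median
absolute separation over the six axis-adjacent pairs of fixation
medians (within-row pairs for x, within-column pairs for y), divided
by the grid's angular separation on that axis. Additive offsets
cancel, so the unknown origin is irrelevant; a multiplicative gain `g`
in the signal yields a ratio of exactly `g` in the noise-free limit —
this identity is the package's main recovery test.

### Precision ratio

The median within-fixation standard deviation divided by the median
adjacent separation of fixation medians. Both numerator and
denominator share the signal's unit, so the ratio is invariant under
any affine rescaling of the whole recording and comparable between
degree-valued and normalized-coordinate estimators. The spread
estimator is the sample SD of the signal (the common alternative,
sample-to-sample RMS, is not used). As samples per fixation grow the
ratio converges to `σ/d` — noise SD over separation — which the
validation script checks at 10⁴ samples per fixation.

### Data loss and blinks

Data loss is simply `100 × invalid / total`. Calibration-free
estimators typically keep reporting while the eyes are closed, so
blinks do not appear as loss but as sharp transients on the vertical
channel. `flag_blinks()` marks intervals where `|Δy/Δt|` between
consecutive valid samples exceeds a threshold (default 200 units/s:
well above fixation noise at 60 Hz, well below a multi-degree
transient traversed within a frame) and merges flags closer than
0.2 s, so the closure and reopening spikes of one blink form one
interval. The threshold is a documented heuristic, not a validated
blink detector.

### The grid simulator

`simulate_grid_session()` draws, per stimulus point with true angles
`(θx, θy)`,

```
x = gain_x · θx + offset_x + N(0, noise_sd_x²)
```

and analogously for y; blink events (Poisson, default 2/min) add
`blink_amplitude` (default −10°) to y for `blink_duration` (default
0.15 s) while the samples stay *valid*; missingness is a separate
Bernoulli mechanism (`p_missing`). Default gains are 0.5 / 0.4 —
mid-range of the 0.3–0.7 scale compression calibration-free
estimators show under eyes-only fixation — with the head-and-eyes
fixation style represented purely as a different gain/offset
configuration (0.9 / 0.7 in `run_experiment1()`'s defaults); no head
pose is simulated. Individual recordings vary around the condition
base with log-normal gain factors (sd 0.15) and normal offsets
(sd 2°), so condition medians recover the base gains while recordings
scatter realistically. The same seed gives bit-identical sessions;
each generator call seeds its own RNG state and leaves the global
state untouched.

## 3. Infant sessions: segmentation, dwells, agreement

### The generative model

`simulate_infant_session()` emulates a 90-s free-looking session at
30 Hz in a sparse scene: three horizontally separated AOIs (left lamp,
parent, right lamp, defaults at −20°, 0°, +20°) plus a residual
"none" state. The state sequence alternates (no self-transitions)
with next-state probabilities from `transition_weights`; state
durations are log-normal (median 1.8 s, log-sd 0.6) truncated below
at 0.3 s. During an AOI dwell the horizontal estimate is
`N(mean_a, noise_sd²)` (default noise 2°); during "none" it falls in
one of two flat off-scene bands centred at ±45° with half-width 16°.
The bands are deliberately bounded: off-scene looking then never lands
inside an AOI section, which makes the noise-free pipeline-recovery
property exact rather than approximate. A zero-centred "broad" none
distribution would sit on top of the parent AOI and make exact
recovery impossible in principle.

Two further mechanisms mirror how estimator data differ from a human
coder's view of the same video:

* **Estimate transients** ("glitches", default 6/min for 0.12 s):
  a few frames where the estimate shoots into the off-scene bands,
  as happens during blinks. The ground-truth coding ignores them —
  a coder watching the video codes through a blink — but the
  estimator pipeline cannot, and the ≥ 3-frame ones break dwells.
  This is the mechanism behind the relative-total-vs-mean-duration
  agreement contrast below; without it, simulated estimator dwells
  would never break.
* **Frame-quantised ground truth**: the manual-coding file is rebuilt
  from per-frame state labels (a dwell starts at the timestamp of its
  first frame; the last dwell ends at the session duration), because
  a human coder steps through video frames. A trailing partial state
  shorter than the minimum dwell is absorbed into its predecessor.
  Timestamps carry small jitter (sd 2 ms) since webcams do not tick
  perfectly; both sides of the comparison use the same timestamps, so
  jitter does not by itself create disagreement.

`degrade_manual_coding()` adds coder boundary uncertainty: interior
dwell boundaries are jittered by `N(0, sd²)` (pipeline default
0.05 s) under order and contiguity constraints; endpoints never move.

`simulate_infant_cohort()` adds between-participant variation —
Dirichlet-perturbed looking preferences (concentration 8),
a normal participant effect on the log dwell-duration level (sd 0.3),
small AOI-position shifts (sd 1.5°) and a log-normal noise factor
(sd 0.2) — because agreement coefficients are meaningless without
genuine between-participant variance. It can also inject the two
exclusion pathways of a real infant study: participants whose video
cannot be coded at all, and participants whose estimates lack spatial
separation (collapsed AOI means with inflated noise), which the
segmentation excludes for having fewer than two discernible peaks.

### Histogram segmentation

AOI boundaries are inferred from the histogram of all horizontal gaze
angles of a session (bin width 1°, well below the simulated 20° AOI
separation; only the horizontal axis is used because the AOIs are
horizontally separated and vertical estimates are the weaker channel).
The original procedure divided these histograms by eye; `segment_aois()`
is a reproducible surrogate with every knob exposed:

1. Pad the histogram with three smoothing-bandwidths of empty bins —
   the density is zero outside the observed range, and without the
   pad a mode flush against the data edge never develops the low
   shoulder that prominence and floor-trimming rely on.
2. Smooth the counts with a Gaussian kernel (bandwidth 2°).
3. Find local maxima and their topographic prominence; peaks with
   prominence ≥ 10% of the global maximum count as *discernible*.
4. Fewer than 2 discernible peaks → the participant is excluded
   (a result, not an error). Exactly 2 → the peaks become the two
   lamps (the lamps are the engaging stimuli) and the space between
   them is assumed to be the parent section. Three or more → the
   three most prominent peaks, left to right, are the three AOIs.
5. Sections run valley-to-valley but are trimmed wherever the
   smoothed density falls below 2% of its maximum, so sparse tails
   between and outside peaks belong to a "none" region; growth is
   additionally bounded by the valley toward any neighbouring mode
   (discernible or not), so a section never invades the off-scene
   band next to it.

Samples inside a section get its label; all others — including
invalid samples — are "none".

### Dwell detection

Estimator dwells use a hysteresis rule: a dwell on AOI `a` ends only
when ≥ `switch_frames` (default 3) consecutive frames carry one other
label `b`, and the dwell on `b` then starts at the first frame of that
run. Shorter excursions do not break the dwell and their frames stay
inside it (the enclosing dwell's duration includes them — the
alternative of excising them would leave dwells non-contiguous).
"None" is an ordinary label here: it can break a dwell and forms
dwells of its own, so the four relative totals partition the session.
The rule counts frames, not seconds, matching frame-based coding at
the native rate even under timestamp jitter. With `switch_frames = 1`
the rule reduces to run-length encoding, which the tests exploit as a
brute-force oracle. Manual-coding files convert to dwells one-to-one
with no hysteresis — the coder already had the surrounding context.

### Measures and agreement

Per AOI: relative total dwell time (summed durations ÷ session
duration), mean dwell duration, and dwell count. An AOI with no
dwells reports its mean duration as absent, never 0 — a fabricated 0
would bias agreement; such participants are dropped pairwise for that
AOI's ICC with the count recorded.

Agreement uses ICC(A,1): two-way random effects, absolute agreement,
single measures, from the ANOVA mean squares (subjects × methods).
Absolute agreement is the right variant because a systematic offset
between estimator and coder is a real disagreement; the tests verify
that an offset lowers ICC while leaving Pearson correlation at 1.
The 95% CI uses the F-based construction with a Satterthwaite
denominator df; the test of ICC > 0 uses `F = MS_R/MS_E` with
`df1 = n − 1`, `df2 = (n − 1)(k − 1)` (the McGraw–Wong convention;
one-way conventions report `n(k − 1)` and differ by one). Reliability
labels (poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤ excellent) are
applied to the CI bounds rather than the point estimate — the
conservative reading for small samples. Implementation note: the mean
squares come from `stats::anova(lm(...))`; the test suite recomputes
them by direct arithmetic as an independent oracle, and a fixed
reference table is additionally checked against values computed with
an external ICC implementation.

### What the pipelines show

`run_experiment2()` on the default cohort reproduces the
characteristic pattern of estimator-vs-coder comparisons: relative
total dwell time agrees well (the brief mislabeled stretches largely
cancel within a session), while mean dwell duration agrees poorly and
is systematically shorter on the estimator side, because transients
break estimator dwells that a coder codes through. The validation
script and acceptance tests quantify this on cohorts where every
participant runs at the same base configuration, so the contrast is
attributable to the measurement pipeline rather than to cohort
composition.

## 4. Numerical choices and problem sizes

* Degenerate inputs: empty recordings, blocks without valid samples,
  zero adjacent separation, excluded segmentations, and
  out-of-session dwells are errors or warnings, never silent `NaN`s.
* Ties and plateaus in peak detection are compressed before the
  local-maximum test; section intervals are half-open `[lo, hi)`
  except the rightmost.
* The truncated log-normal dwell sampler uses rejection (exact), not
  clamping.
* Test and validation problem sizes were chosen so that the full
  suite runs in well under a minute of simulation per property:
  100 seeds for gain recovery, 10⁴ samples per fixation for the
  precision limit, 200 random label sequences for the dwell-rule
  oracle, cohorts of 8–25 for pipeline recovery and 44 for the
  exclusion accounting.

## 5. Known limitations

* The synthetic sessions contain no saccade dynamics within dwells,
  no head-pose-dependent errors, no drift, and no autocorrelated
  noise; passing recovery tests shows the statistics are implemented
  correctly, not that any real estimator meets them.
* The prominence-based peak rule is a surrogate for by-eye judgment.
  It shares that judgment's failure mode: a participant who rarely
  visits one AOI can leave its peak below the discernibility
  threshold while broad off-scene looking forms a competing mode, and
  the resulting mislabeling moves relative total dwell time between
  that AOI and "none". In a heterogeneous cohort an occasional
  extreme-preference participant can therefore depress the
  relative-total ICC for the outer AOIs.
* The two-peak fallback assumes the lamps dominate; a participant
  whose two discernible peaks are actually the parent and one lamp is
  mislabeled by construction.
* Absolute accuracy in degrees relative to true stimulus positions is
  out of scope — without a known origin it cannot be computed; the
  scale and precision ratios are the operable substitutes.
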