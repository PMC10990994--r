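#!/usr/bin/env Rscript
# Infant free-looking study: AOI segmentation, dwell detection, and
# agreement between estimator-derived measures and manual coding.
#
# Simulates a 44-infant cohort (14 uncodable, 5 without discernible
# spatial structure), runs the segmentation + hysteresis-dwell pipeline
# on every codable participant, and compares per-participant relative
# total dwell times and mean dwell durations against (jittered) manual
# coding with ICC(A,1).

library(gazeqc)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_infant_cohort(n = 44, n_uncodable = 14, n_unimodal = 5,
                                 seed = 2026)
res <- run_experiment2(cohort)

el <- res$exclusion_log
message(sprintf("cohort: %d infants; %d uncodable, %d with <2 discernible peaks, %d included",
                sum(el$n), el$n[el$reason == "uncodable"],
                el$n[el$reason == "too_few_peaks"],
                el$n[el$reason == "included"]))

write.csv(res$participant_table, "results/exp2_participants.csv",
          row.names = FALSE)
write.csv(res$exclusion_log, "results/exp2_exclusion_log.csv",
          row.names = FALSE)
write.csv(res$measures_est, "results/exp2_measures_estimates.csv",
          row.names = FALSE)
write.csv(res$measures_man, "results/exp2_measures_manual.csv",
          row.names = FALSE)
cmp <- res$comparison
write.csv(cmp[, setdiff(names(cmp), "icc_result")],
          "results/exp2_agreement.csv", row.names = FALSE)

message("agreement (ICC A,1) by AOI and measure:")
print(as.data.frame(cmp[, c("aoi", "measure", "icc", "ci_low", "ci_high",
                            "p", "interpretation")]), digits = 2)
rel <- cmp[cmp$measure == "relative_total", ]
dur <- cmp[cmp$measure == "mean_duration", ]
message(sprintf(
  "relative total dwell time agrees well (median ICC %.2f) while mean dwell duration does not (median ICC %.2f): estimator dwells break where the coder codes through",
  median(rel$icc), median(dur$icc, na.rm = TRUE)))

# Fig-8-style histogram for the first included participant
inc <- res$participant_table$participant[res$participant_table$status ==
                                           "included"][1]
p_inc <- Filter(function(p) p$id == inc, cohort$participants)[[1]]
h <- build_histogram(p_inc$session$recording$samples$x)
ggplot2::ggsave("results/figures/aoi_histogram_example.png",
                plot_aoi_histogram(h, res$segmentations[[inc]]),
                width = 6, height = 4, dpi = 120)
# paired per-participant comparison
ggplot2::ggsave("results/figures/paired_relative_total.png",
                plot_paired_measures(res$measures_est, res$measures_man,
                                     "relative_total"),
                width = 8, height = 3.5, dpi = 120)
ggplot2::ggsave("results/figures/paired_mean_duration.png",
                plot_paired_measures(res$measures_est, res$measures_man,
                                     "mean_duration"),
                width = 8, height = 3.5, dpi = 120)
message("wrote results/exp2_*.csv and results/figures/*")
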