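#!/usr/bin/env Rscript
# Condition-level summary tables: accuracy and confidence by modality,
# percept fractions for McGurk and unisensory selections, causal-response
# fractions, the median split by causal confidence, metamer selection, and
# voicing accuracy. One tidy CSV per table, one row per subject x cell.

suppressPackageStartupMessages({
  library(mcgurkci)
  library(readr)
})

trials <- read_trials("results/trials_normalized.csv")
wr <- function(tab, name) {
  write_csv(tab, file.path("results", name), na = "")
  cat("wrote results/", name, " (", nrow(tab), " rows)\n", sep = "")
}

acc <- accuracy_and_confidence_by_modality(trials)
wr(acc, "summary_accuracy_confidence_by_modality.csv")
cat("\nMean 6-way accuracy by modality (across subjects):\n")
print(aggregate_subjects(acc, "accuracy", keys = "modality")[, c("modality", "mean")])

wr(percept_fractions(trials, "mcgurk"), "summary_percepts_mcgurk.csv")
wr(percept_fractions(trials, "auditory_bp"), "summary_percepts_auditory_bp.csv")
wr(percept_fractions(trials, "visual_gk"), "summary_percepts_visual_gk.csv")

byc <- causal_fractions_and_confidence(trials, "correctness")
byp <- causal_fractions_and_confidence(trials, "percept")
wr(byc, "summary_causal_by_correctness.csv")
wr(byp, "summary_causal_by_percept.csv")
c1 <- byp[byp$causal_response == "C=1", ]
cat("\nC=1 fraction by McGurk percept (across subjects):\n")
print(aggregate_subjects(c1, "fraction", keys = "level")[, c("level", "mean")])

wr(median_split_by_causal_confidence(trials), "summary_median_split.csv")
wr(suppressWarnings(select_metamers(trials)), "summary_metamers.csv")

voi <- voicing_accuracy(trials)
wr(voi, "summary_voicing_accuracy.csv")
cat("\nVoicing accuracy by condition (across subjects):\n")
print(aggregate_subjects(voi, "accuracy", keys = "condition")[, c("condition", "mean")])
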