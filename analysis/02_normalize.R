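#!/usr/bin/env Rscript
# Normalize the perceptual (4-level) and causal (continuous) confidence
# reports per subject with the cumulative-distribution transform, so that
# every subject's normalized confidence has mean 0.5 and full-range spread.

suppressPackageStartupMessages(library(mcgurkci))

trials <- read_trials("results/trials.csv")
trials <- add_normalized_confidence(trials)
write_trials(trials, "results/trials_normalized.csv")

by_subj <- tapply(trials$perceptual_confidence_norm, trials$subject, mean)
cat("Per-subject mean normalized perceptual confidence (should all be 0.5):\n")
print(round(by_subj, 10))
av <- trials[trials$modality == "AV", ]
cat("Per-subject mean normalized causal confidence:\n")
print(round(tapply(av$causal_confidence_norm, av$subject, mean), 10))
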