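Package: mcgurkci
Title: Bayesian Causal Inference Observer for Audiovisual Speech with
    Perceptual and Causal Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Bayesian causal inference observer for audiovisual
    syllable categorization along the place-of-articulation axis: reliability
    weighted fusion, segregation, the posterior over common versus independent
    causes, model averaging, categorical readout over B/P, D/T and G/K, and
    latent perceptual and causal confidence. Includes a synthetic dual-report
    McGurk experiment generator (16 blocks of 144 trials; congruent, McGurk and
    unisensory conditions; 4-level perceptual confidence and continuous causal
    confidence), a tie-aware cumulative-distribution confidence normalization,
    the condition-level summary statistics of a dual-report design (accuracy
    and confidence by modality, percept and causal-response fractions, median
    splits by causal confidence, metamer selection, voicing accuracy), and
    Monte-Carlo maximum-likelihood parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
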