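---
title: "A Bayesian causal-inference observer for audiovisual syllable perception, with perceptual and causal confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian causal-inference observer for audiovisual syllable perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcgurkci)
```

## The model

When a spoken syllable and the speaker's lip movements arrive together, the
observer faces two coupled inferences: *what* syllable was spoken, and
*whether* the auditory and visual signals came from a common source at all.
`mcgurkci` implements the standard Bayesian causal-inference account of this
problem on a one-dimensional place-of-articulation axis, where labial
consonants (B/P) sit at $-1$, dentals (D/T) at $0$ and gutturals (G/K) at
$+1$.

On each audiovisual trial the observer receives noisy internal signals
$x_A \sim N(S_A, \sigma_A^2)$ and $x_V \sim N(S_V, \sigma_V^2)$. Under a
common cause ($C=1$) the optimal estimate fuses the signals weighted by
their reliabilities $r = 1/\sigma^2$:

$$\hat S_{AV} = w_A x_A + w_V x_V,\qquad
  w_A = \frac{r_A}{r_A + r_V},\qquad
  \mathrm{Var} = \frac{1}{r_A + r_V}.$$

Under independent causes ($C=2$) the task-relevant estimate is the auditory
signal alone (segregation). The causal structure itself is inferred from the
signals by Bayes' rule,

$$P(C=1 \mid x_A, x_V) =
  \frac{\pi\, m_1}{\pi\, m_1 + (1-\pi)\, m_2},$$

where $\pi$ is the causal prior, $m_1$ integrates the product of the two
likelihoods over a shared source location, and $m_2$ is the product of the
two single-signal marginals. The final percept *model-averages* the fusion
and segregation posteriors weighted by $P(C \mid x_A, x_V)$, producing a
two-component Gaussian mixture over the place axis. Integrating that mixture
between the category boundaries ($-0.5$ and $+0.5$) yields a three-category
posterior over B/P, D/T and G/K; its argmax is the reported percept and
$P(C=1\mid x_A,x_V) \ge 0.5$ the reported causal decision.

Because percept and causal judgement derive from the same posterior
quantities, the model predicts their confidences to be coupled across
trials — the package's simulations reproduce that coupling, and the summary
module measures it.

### A proper flat prior

A genuinely flat prior over an unbounded axis leaves the independent-cause
marginal $m_2$ undefined (it scales with the inverse support width, which
the common-cause marginal does only once). We therefore make the prior
proper as a bounded uniform on $[-L, L]$, default $L = 3$: wide enough to
cover the stimulus classes at $\pm 1$ and any realistic sensory sample, and
narrow enough that the marginals remain informative. $L$ is an explicit
parameter of `observer_params()`; the causal posterior depends on it (larger
$L$ penalizes the independent-cause model more), so all quantitative outputs
are reported at the stated default. Each Gaussian component is renormalized
on $[-L, L]$; category masses use closed-form normal CDF differences, which
the test suite cross-checks against trapezoid quadrature with at least
$10^4$ grid points to $10^{-6}$.

### Latent confidence

The theoretical literature offers several readouts of confidence from a
posterior, and the behavioural data this design produces cannot adjudicate
between them. Three are implemented and selectable via
`confidence_rule`:

* `"chosen-posterior"` (default) — the posterior probability of the chosen
  category;
* `"neg-entropy"` — $1 - H(\text{category posterior})/\log 3$;
* `"top-two-difference"` — the gap between the two most probable categories.

Latent causal confidence is $2\max(p_{C1}, 1 - p_{C1}) - 1 \in [0, 1]$, the
distance of the causal posterior from indifference. On unisensory trials
causal quantities are reported as absent (`NA`), never as zero.

### Deterministic tie rules

Exact ties are resolved deterministically so that every run is
reproducible: tied category maxima go to the category containing the
posterior mean (falling back to the first tied category if the mean lies
elsewhere); $p_{C1} = 0.5$ resolves to $C=1$; conflicting voicing votes go
to the more accurate channel, and to the auditory channel at exactly equal
accuracies. The causal threshold is fixed at $0.5$ (maximum a posteriori
structure); no response-bias parameter is included.

## The synthetic experiment

`build_design()` reproduces the dual-report session structure exactly: 16
main blocks of 144 trials — 36 visual-only, 36 auditory-only, 36
audiovisual-congruent (two repetitions of each of the 18 syllables: 6
consonants × 3 vowels) and 36 McGurk trials (six repetitions of each of the
6 cross-dubbed identities, auditory B + visual G and auditory P + visual K
over three vowels) — preceded by a 54-trial familiarization block (18
congruent, then 18 auditory, then 18 visual, each syllable once). Congruent
and McGurk trials are randomly interleaved; unisensory trials sit in
separate 18-trial mini-blocks. All counts are exact by construction and the
ordering is reproducible from the seed.

`simulate_observer()` then runs the observer at the generative settings
$S_A = -1$, $S_V = +1$, $\sigma_A^2 = \sigma_V^2 = 0.73$, $\pi = 0.5$ on
every trial. Three mechanisms extend the place-axis model to the full
response space:

* **Voicing channel.** The place axis cannot carry the voiced/unvoiced
  distinction, so voicing is modelled as an independent two-channel
  Bernoulli process with per-channel accuracies, combined across modalities
  by Bayes (equivalently: agreeing votes win; conflicts go to the more
  reliable channel). Defaults `voicing_acc_A = 0.85`, `voicing_acc_V = 0.5`
  make lipreading uninformative about voicing, which is what drives
  visual-only 6-way accuracy far below place accuracy and produces the
  characteristic chance-level voicing performance on visual-only trials.
  On McGurk trials the auditory component defines the correct voicing (the
  two components share a voicing class by construction).
* **Lapses.** With probability `lapse_rate` (default 0.03, a typical
  attentional lapse rate for long psychophysical sessions) a trial's
  consonant response, confidence level and causal report are uniform
  random. This is the simplest mechanism consistent with the observation
  that erroneous high-certainty responses behave like random guesses.
* **Confidence scales.** The latent perceptual confidence is mapped to the
  4-level report scale at the subject's own empirical quartiles over
  non-lapse trials — a subject instructed to use the whole scale will; fixed
  cut points would starve levels. The continuous causal report equals the
  latent causal confidence. Both mappings are conventions of this package:
  the mapping from latent confidence to an overt scale is not constrained
  by the model.

One simulated subject corresponds to one seed; `simulate_experiment()`
varies seeds across subjects.

### What the generator does and does not emulate

The generator reproduces the design's structure, response spaces and the
model's trial-to-trial stochasticity. It does not emulate acoustic noise
ramps on the recordings, stimulus-specific idiosyncrasies (a particular
speaker's /ga/), serial dependencies, fatigue, or between-subject parameter
variation (all subjects share one parameter set unless seeds and parameters
are varied explicitly). Passing tests therefore demonstrate internal
consistency of the method and correctness of the selection/aggregation
logic — not that any particular human dataset satisfies the model. Notably,
at equal auditory and visual reliabilities the simulated McGurk percepts are
predominantly B/P (auditory-dominant); the strong G/K dominance seen in
human McGurk data arises when auditory reliability is degraded, i.e. larger
`sigma2_A`, which shifts weight toward the visual signal.

## Confidence normalization

Raw confidence distributions differ across subjects in mean and spread. The
package normalizes each subject's reports with the cumulative-distribution
transform
$$\mathrm{normalized}(x) = \tfrac12\left[P(X < x) + P(X \le x)\right],$$
computed against the subject's own empirical distribution, with tied values
sharing the average of their normalized values. This is exactly
$(\bar r - 0.5)/n$ in average ranks, so the normalized mean is exactly 0.5
for every input, outputs lie strictly inside $(0,1)$, and any strictly
increasing distortion of the raw scale is removed. If 30% of reports share
the maximum, all of them map to $(0.7 + 1)/2 = 0.85$. Normalization is per
subject and per confidence type by default (`pool = TRUE` pools subjects);
it is applied to both the 4-level perceptual scale and the continuous
causal scale.

## Summary tables

The summary module reproduces the selection logic behind the standard
results panels of a dual-report design: accuracy and confidence by modality
split by correctness; percept fractions over B/P–D/T–G/K for McGurk,
auditory-B/P and visual-G/K selections; causal-response fractions and
causal confidence grouped by correctness (congruent) or percept (McGurk); a
per-subject median split by causal confidence (ties to the low stratum, a
deterministic choice); metamer selection (congruent trials with correct
syllable and $C=1$ versus McGurk trials with correct voicing and $C=1$,
matched within percept class); and voicing accuracy by condition.

Aggregation is subject-level first: each summary emits one row per subject
and cell, and `aggregate_subjects()` averages the per-subject values,
retaining quantiles for box-plot-style presentation. On congruent trials
"correct" is the full 6-way consonant by default, but place-only accuracy is
computed alongside under its own label, since the two diverge exactly where
the voicing channel is uninformative. Inferential statistics (mixed models)
are deliberately out of scope; the tables are tidy and ready for external
model fitting.

## Likelihood and parameter recovery

Although the model is not fitted to human data here, the package carries a
full likelihood so that recovery can be verified on synthetic data.
`trial_loglik()` computes a Monte-Carlo marginal likelihood of the discrete
joint response — consonant × causal report on audiovisual trials, consonant
alone on unisensory trials — by pushing signal samples through the observer
and tallying response cells, mixed with the uniform lapse distribution
(1/12 or 1/6 per cell). Confidence reports are excluded from the
likelihood: their latent-to-report mapping is a package convention, and
conditioning on it would fit the convention, not the model.

Standard-normal draws are fixed by the seed and reused at every parameter
evaluation (common random numbers), scaled by the candidate
$\sigma$ — making the Monte-Carlo surface deterministic and smooth enough for
bounded derivative-free search (Nelder–Mead on a logit-transformed box).
Cell probabilities are floored at $10^{-12}$ so a zero-probability response
under `lapse_rate = 0` yields a large finite penalty and a flag rather than
$-\infty$.

With one simulated session set (2,304 main trials) at the generative
defaults, the test suite requires median recovery errors below 0.2 for the
variances and 0.1 for the causal prior over ten seeds; in practice the
errors are several times smaller. Problem sizes throughout the tests (block
counts, Monte-Carlo draws per condition, seed counts) were chosen as the
smallest that make the checked contrasts statistically unambiguous.

## Numerical choices

* All integrals over the place axis are error-function closed forms;
  quadrature appears only in test oracles.
* Tolerances: category posteriors sum to 1 within $10^{-9}$; closed-form vs
  quadrature agreement within $10^{-6}$; mirror symmetry of the place axis
  within $10^{-12}$.
* The bounded-uniform support must strictly contain both category
  boundaries; configurations violating this (or any parameter range) are
  rejected at construction, before any stage runs.
* All randomness flows from explicit integer seeds; regenerating a design,
  a simulation or a likelihood from the same seed is bit-identical.

## Known limitations

* The place axis is one-dimensional; a two-dimensional phoneme–viseme space
  is explicitly out of scope.
* The causal prior is fixed per observer, not estimated per stimulus
  identity; real observers may adapt it across blocks.
* The voicing channel is independent of the place axis by construction, so
  correlations between place errors and voicing errors cannot arise except
  through lapses.
* Printed illustration values from the literature that were computed under
  an improper flat prior are reproduced here only up to the choice of $L$;
  the package documents its own $L = 3$ results and cross-checks them
  against quadrature rather than against printed bar heights.
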