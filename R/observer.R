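#' Observer parameters for the causal-inference model
#'
#' Bundles every parameter of the Bayesian causal inference observer on the
#' place-of-articulation axis. Labial consonants (B/P) sit at -1, dental (D/T)
#' at 0 and guttural (G/K) at +1; the flat prior over place is made proper as
#' a bounded uniform on `[-L, L]`.
#'
#' @param sA place coordinate of the auditory source class (default -1, the
#'   auditory component of a McGurk pair).
#' @param sV place coordinate of the visual source class (default +1).
#' @param sigma2_A,sigma2_V auditory and visual noise variances on the place
#'   axis (both 0.73 by default).
#' @param p_common prior probability of a common cause, in `[0, 1]`.
#' @param L half-width of the bounded-uniform prior over place; must exceed
#'   both category boundaries in absolute value.
#' @param boundary_lo,boundary_hi category boundaries separating B/P from D/T
#'   and D/T from G/K (defaults -0.5 and +0.5).
#' @param confidence_rule latent perceptual-confidence readout: the posterior
#'   probability of the chosen category (`"chosen-posterior"`), one minus the
#'   normalized entropy of the category posterior (`"neg-entropy"`), or the
#'   difference between the two most probable categories
#'   (`"top-two-difference"`).
#' @param lapse_rate probability of an attention-lapse trial producing uniform
#'   random reports, in `[0, 1)`... `1` is allowed for degenerate simulations.
#' @param voicing_acc_A,voicing_acc_V accuracy of the auditory and visual
#'   voicing channels in `[0.5, 1]`; voicing is carried by a channel separate
#'   from the place axis (visual default 0.5: lipreading is uninformative
#'   about voicing).
#'
#' @return An object of class `observer_params` (a validated named list).
#' @examples
#' p <- observer_params()
#' p$sigma2_A
#' @export
observer_params <- function(sA = -1, sV = 1,
                            sigma2_A = 0.73, sigma2_V = 0.73,
                            p_common = 0.5, L = 3,
                            boundary_lo = -0.5, boundary_hi = 0.5,
                            confidence_rule = c("chosen-posterior",
                                                "neg-entropy",
                                                "top-two-difference"),
                            lapse_rate = 0.03,
                            voicing_acc_A = 0.85, voicing_acc_V = 0.5) {
  confidence_rule <- match.arg(confidence_rule)
  p <- structure(list(
    sA = sA, sV = sV,
    sigma2_A = sigma2_A, sigma2_V = sigma2_V,
    p_common = p_common, L = L,
    boundary_lo = boundary_lo, boundary_hi = boundary_hi,
    confidence_rule = confidence_rule,
    lapse_rate = lapse_rate,
    voicing_acc_A = voicing_acc_A, voicing_acc_V = voicing_acc_V
  ), class = "observer_params")
  validate_observer_params(p)
}

#' @rdname observer_params
#' @param x an `observer_params` object.
#' @export
validate_observer_params <- function(x) {
  stopifnot(inherits(x, "observer_params"))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(x$sigma2_A) || x$sigma2_A <= 0) stop("sigma2_A must be > 0")
  if (!num1(x$sigma2_V) || x$sigma2_V <= 0) stop("sigma2_V must be > 0")
  if (!num1(x$p_common) || x$p_common < 0 || x$p_common > 1)
    stop("p_common must lie in [0, 1]")
  if (!num1(x$L) || x$L <= 0) stop("invalid prior support: L must be > 0")
  if (x$L <= max(abs(x$boundary_lo), abs(x$boundary_hi)))
    stop("configuration error: prior half-width L must exceed both category boundaries")
  if (x$boundary_lo >= x$boundary_hi) stop("boundary_lo must be < boundary_hi")
  if (!num1(x$lapse_rate) || x$lapse_rate < 0 || x$lapse_rate > 1)
    stop("lapse_rate must lie in [0, 1]")
  for (f in c("voicing_acc_A", "voicing_acc_V"))
    if (!num1(x[[f]]) || x[[f]] < 0.5 || x[[f]] > 1)
      stop(f, " must lie in [0.5, 1]")
  x
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Bayesian causal inference observer\n")
  cat(sprintf("  sources      : sA = %g, sV = %g on [-L, L], L = %g\n", x$sA, x$sV, x$L))
  cat(sprintf("  noise        : sigma2_A = %g, sigma2_V = %g\n", x$sigma2_A, x$sigma2_V))
  cat(sprintf("  causal prior : P(C=1) = %g\n", x$p_common))
  cat(sprintf("  boundaries   : B/P | D/T at %g, D/T | G/K at %g\n",
              x$boundary_lo, x$boundary_hi))
  cat(sprintf("  confidence   : %s; lapse %g; voicing acc A %g / V %g\n",
              x$confidence_rule, x$lapse_rate, x$voicing_acc_A, x$voicing_acc_V))
  invisible(x)
}

#' One trial's noisy internal signals
#'
#' @param xA auditory signal on the place axis, or `NA` on visual-only trials.
#' @param xV visual signal on the place axis, or `NA` on auditory-only trials.
#' @return An object of class `sensory_sample`.
#' @examples
#' sensory_sample(xA = -1.45, xV = 2.20)
#' @export
sensory_sample <- function(xA = NA_real_, xV = NA_real_) {
  if (is.na(xA) && is.na(xV)) stop("at least one of xA, xV must be present")
  if ((!is.na(xA) && !is.finite(xA)) || (!is.na(xV) && !is.finite(xV)))
    stop("signals must be finite")
  structure(list(xA = xA, xV = xV), class = "sensory_sample")
}

# one truncated-Gaussian mixture component on [-L, L]
gaussian_component <- function(mean, var, weight = 1, lo, hi) {
  stopifnot(var > 0, weight >= 0, weight <= 1)
  structure(list(mean = mean, var = var, weight = weight, lo = lo, hi = hi),
            class = "gaussian_component")
}

#' Reliability-weighted fusion posterior under a common cause
#'
#' Combines the auditory and visual signals with weights proportional to their
#' precisions \eqn{r = 1/\sigma^2}: mean \eqn{w_A x_A + w_V x_V} with
#' \eqn{w_A = r_A / (r_A + r_V)}, variance \eqn{1/(r_A + r_V)}, truncated to
#' the prior support for downstream integration.
#'
#' @param sample a [sensory_sample()] with both signals present.
#' @param params an [observer_params()] object.
#' @return A `gaussian_component` (mean, var, weight, truncation bounds).
#' @examples
#' fused_posterior(sensory_sample(-1.45, 2.20), observer_params())
#' @export
fused_posterior <- function(sample, params) {
  if (is.na(sample$xA) || is.na(sample$xV))
    stop("fusion is undefined for unisensory input: both xA and xV are required")
  rA <- 1 / params$sigma2_A
  rV <- 1 / params$sigma2_V
  gaussian_component(
    mean = (rA * sample$xA + rV * sample$xV) / (rA + rV),
    var = 1 / (rA + rV),
    weight = 1, lo = -params$L, hi = params$L
  )
}

#' Segregation posterior under independent causes
#'
#' Under independent causes each signal is attributed to its own source; with
#' the bounded-uniform prior the posterior over that source equals the
#' likelihood renormalized on `[-L, L]`. The auditory-report task reads out
#' the auditory component.
#'
#' @inheritParams fused_posterior
#' @param modality `"auditory"` or `"visual"`: which source to report.
#' @return A `gaussian_component`.
#' @examples
#' segregated_posterior(sensory_sample(xA = -1.45), observer_params(), "auditory")
#' @export
segregated_posterior <- function(sample, params,
                                 modality = c("auditory", "visual")) {
  modality <- match.arg(modality)
  x <- if (modality == "auditory") sample$xA else sample$xV
  if (is.na(x))
    stop("unisensory mismatch: requested ", modality,
         " signal is absent from this sample")
  v <- if (modality == "auditory") params$sigma2_A else params$sigma2_V
  gaussian_component(mean = x, var = v, weight = 1,
                     lo = -params$L, hi = params$L)
}

# marginal likelihood pieces under the bounded-uniform prior, closed form.
# m1: common cause  — integral over s in [-L, L] of (1/2L) N(xA; s, sA2) N(xV; s, sV2)
# m2: independent   — product of the two single-signal marginals
.marginal_c1 <- function(xA, xV, sigma2_A, sigma2_V, L) {
  vf <- 1 / (1 / sigma2_A + 1 / sigma2_V)
  mf <- (xA / sigma2_A + xV / sigma2_V) * vf
  stats::dnorm(xA - xV, 0, sqrt(sigma2_A + sigma2_V)) / (2 * L) *
    (stats::pnorm((L - mf) / sqrt(vf)) - stats::pnorm((-L - mf) / sqrt(vf)))
}

.marginal_single <- function(x, sigma2, L) {
  (stats::pnorm((L - x) / sqrt(sigma2)) - stats::pnorm((-L - x) / sqrt(sigma2))) / (2 * L)
}

#' Posterior probability of a common cause
#'
#' \eqn{P(C=1 \mid x_A, x_V)} by Bayes' rule over the two causal structures,
#' with the marginal likelihoods integrated in closed form (error functions)
#' against the bounded-uniform place prior.
#'
#' @inheritParams fused_posterior
#' @return A probability in `[0, 1]`.
#' @examples
#' causal_posterior(sensory_sample(0, 0), observer_params())     # ~0.66
#' causal_posterior(sensory_sample(-1.45, 2.20), observer_params()) # ~0.02
#' @export
causal_posterior <- function(sample, params) {
  if (is.na(sample$xA) || is.na(sample$xV))
    stop("causal inference requires both signals")
  if (params$L <= 0) stop("invalid prior support")
  pc <- params$p_common
  if (pc == 1) return(1)
  if (pc == 0) return(0)
  m1 <- .marginal_c1(sample$xA, sample$xV, params$sigma2_A, params$sigma2_V, params$L)
  m2 <- .marginal_single(sample$xA, params$sigma2_A, params$L) *
    .marginal_single(sample$xV, params$sigma2_V, params$L)
  pc * m1 / (pc * m1 + (1 - pc) * m2)
}

#' Model-averaged posterior over the auditory source
#'
#' The final percept averages fusion and segregation, weighted by the causal
#' posterior: a two-component truncated-Gaussian mixture
#' \eqn{P(S_A|x_A,x_V) = \sum_C P(S_{AV}|C,x_A,x_V) P(C|x_A,x_V)}.
#'
#' @inheritParams fused_posterior
#' @return A list of class `mixture_posterior`: `gaussian_component`s whose
#'   weights sum to 1, plus the causal posterior as attribute `p_c1`.
#' @export
model_average_posterior <- function(sample, params) {
  p1 <- causal_posterior(sample, params)
  fus <- fused_posterior(sample, params)
  seg <- segregated_posterior(sample, params, "auditory")
  fus$weight <- p1
  seg$weight <- 1 - p1
  structure(list(fus, seg), class = "mixture_posterior", p_c1 = p1)
}

# mass of one truncated component between a and b (within [lo, hi])
.trunc_mass <- function(comp, a, b) {
  s <- sqrt(comp$var)
  z <- stats::pnorm((comp$hi - comp$mean) / s) - stats::pnorm((comp$lo - comp$mean) / s)
  (stats::pnorm((b - comp$mean) / s) - stats::pnorm((a - comp$mean) / s)) / z
}

#' Mixture density on the place axis
#'
#' @param posterior a `mixture_posterior` or single `gaussian_component`.
#' @param s grid of place coordinates.
#' @return Density values; zero outside the truncation bounds.
#' @export
posterior_density <- function(posterior, s) {
  comps <- if (inherits(posterior, "gaussian_component")) list(posterior) else posterior
  out <- numeric(length(s))
  for (comp in comps) {
    sd <- sqrt(comp$var)
    z <- stats::pnorm((comp$hi - comp$mean) / sd) - stats::pnorm((comp$lo - comp$mean) / sd)
    d <- stats::dnorm(s, comp$mean, sd) / z
    d[s < comp$lo | s > comp$hi] <- 0
    out <- out + comp$weight * d
  }
  out
}

# mixture mean on the truncated support (used by the tie rule)
.posterior_mean <- function(posterior) {
  comps <- if (inherits(posterior, "gaussian_component")) list(posterior) else posterior
  m <- 0
  for (comp in comps) {
    sd <- sqrt(comp$var)
    a <- (comp$lo - comp$mean) / sd
    b <- (comp$hi - comp$mean) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    tm <- comp$mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    m <- m + comp$weight * tm
  }
  m
}

#' Discrete posterior over the three place categories
#'
#' Integrates the continuous posterior between the category boundaries:
#' mass on `[-L, b_lo)` is B/P, `[b_lo, b_hi]` is D/T, `(b_hi, L]` is G/K.
#' Computed per mixture component from Gaussian CDF differences and combined
#' by the mixture weights.
#'
#' @inheritParams posterior_density
#' @param params an [observer_params()] carrying the boundaries and support.
#' @return Named probability vector over `c("B/P", "D/T", "G/K")` summing to 1.
#' @export
category_posterior <- function(posterior, params) {
  if (abs(params$boundary_lo) >= params$L || abs(params$boundary_hi) >= params$L)
    stop("configuration error: category boundaries outside the prior support")
  comps <- if (inherits(posterior, "gaussian_component")) list(posterior) else posterior
  out <- c("B/P" = 0, "D/T" = 0, "G/K" = 0)
  for (comp in comps) {
    out <- out + comp$weight * c(
      .trunc_mass(comp, comp$lo, params$boundary_lo),
      .trunc_mass(comp, params$boundary_lo, params$boundary_hi),
      .trunc_mass(comp, params$boundary_hi, comp$hi)
    )
  }
  out
}

PLACE_LEVELS <- c("B/P", "D/T", "G/K")

# which category does a place coordinate fall in (tie rule helper)
.place_category <- function(s, params) {
  if (s < params$boundary_lo) "B/P" else if (s <= params$boundary_hi) "D/T" else "G/K"
}

.latent_confidence <- function(catp, rule) {
  unname(switch(rule,
    "chosen-posterior" = max(catp),
    "neg-entropy" = {
      nz <- catp[catp > 0]
      1 + sum(nz * log(nz)) / log(3)
    },
    "top-two-difference" = {
      srt <- sort(catp, decreasing = TRUE)
      srt[1] - srt[2]
    },
    stop("unknown confidence rule: ", rule)
  ))
}

#' Full inference for one trial
#'
#' Runs the complete observer on one sensory sample: on audiovisual trials the
#' causal posterior, model-averaged mixture, category posterior, percept,
#' causal decision and both latent confidences; on unisensory trials the
#' single available likelihood is read out with the same prior and category
#' boundaries, and the causal quantities are absent (`NA`).
#'
#' @inheritParams fused_posterior
#' @return An `inference_outcome` list: `p_c1`, `posterior`,
#'   `category_posterior`, `percept`, `causal_decision`,
#'   `perceptual_confidence_latent`, `causal_confidence_latent`.
#' @examples
#' out <- infer_trial(sensory_sample(-1.45, 2.20), observer_params())
#' out$percept
#' @export
infer_trial <- function(sample, params) {
  av <- !is.na(sample$xA) && !is.na(sample$xV)
  if (av) {
    posterior <- model_average_posterior(sample, params)
    p_c1 <- attr(posterior, "p_c1")
  } else {
    modality <- if (is.na(sample$xV)) "auditory" else "visual"
    posterior <- segregated_posterior(sample, params, modality)
    p_c1 <- NA_real_
  }
  out <- list(p_c1 = p_c1, posterior = posterior,
              category_posterior = category_posterior(posterior, params))
  decide_and_confide(out, params)
}

#' Categorical decision, causal decision and latent confidences
#'
#' Completes an inference outcome: the percept is the argmax of the category
#' posterior (exact ties resolve to the category containing the posterior
#' mean); the causal decision is C=1 iff `p_c1 >= 0.5`; latent perceptual
#' confidence follows `params$confidence_rule`; latent causal confidence is
#' `2 * max(p_c1, 1 - p_c1) - 1`.
#'
#' @param outcome a partial outcome with `category_posterior`, `posterior`
#'   and `p_c1` fields (as built by [infer_trial()]).
#' @param params an [observer_params()] object.
#' @return The completed `inference_outcome`.
#' @export
decide_and_confide <- function(outcome, params) {
  catp <- outcome$category_posterior
  mx <- max(catp)
  top <- which(catp >= mx - 1e-12)
  if (length(top) > 1L) {
    mean_cat <- .place_category(.posterior_mean(outcome$posterior), params)
    percept <- if (mean_cat %in% names(catp)[top]) mean_cat else names(catp)[top[1]]
  } else {
    percept <- names(catp)[top]
  }
  outcome$percept <- percept
  outcome$perceptual_confidence_latent <- .latent_confidence(catp, params$confidence_rule)
  if (is.na(outcome$p_c1)) {
    outcome$causal_decision <- NA_character_
    outcome$causal_confidence_latent <- NA_real_
  } else {
    outcome$causal_decision <- if (outcome$p_c1 >= 0.5) "C=1" else "C=2"
    outcome$causal_confidence_latent <- abs(2 * outcome$p_c1 - 1)
  }
  class(outcome) <- "inference_outcome"
  outcome
}

#' Everything drawn in one simulation-figure row
#'
#' For one audiovisual signal pair, returns the likelihood curves on a grid,
#' the fusion and segregation components, the causal posterior, the mixture
#' density, and the discrete category posterior — the full content of one
#' panel row of the model-illustration figure.
#'
#' @param xA,xV the audiovisual signal pair.
#' @param params an [observer_params()] object.
#' @param grid_n number of grid points across `[-L, L]`.
#' @return A list with `grid` (a [tibble::tibble()] of s, likelihood_A,
#'   likelihood_V, density_fusion, density_segregation, density_posterior),
#'   `p_c1`, `category_posterior`, `percept`, and the two components.
#' @export
figure8_panel <- function(xA, xV, params = observer_params(), grid_n = 401) {
  sample <- sensory_sample(xA, xV)
  posterior <- model_average_posterior(sample, params)
  p_c1 <- attr(posterior, "p_c1")
  fus <- posterior[[1]]
  seg <- posterior[[2]]
  s <- seq(-params$L, params$L, length.out = grid_n)
  grid <- tibble::tibble(
    s = s,
    likelihood_A = stats::dnorm(xA, s, sqrt(params$sigma2_A)),
    likelihood_V = stats::dnorm(xV, s, sqrt(params$sigma2_V)),
    density_fusion = posterior_density(gaussian_component(fus$mean, fus$var, 1, fus$lo, fus$hi), s),
    density_segregation = posterior_density(gaussian_component(seg$mean, seg$var, 1, seg$lo, seg$hi), s),
    density_posterior = posterior_density(posterior, s)
  )
  catp <- category_posterior(posterior, params)
  out <- decide_and_confide(list(p_c1 = p_c1, posterior = posterior,
                                 category_posterior = catp), params)
  list(xA = xA, xV = xV, grid = grid, p_c1 = p_c1,
       category_posterior = catp, percept = out$percept,
       causal_decision = out$causal_decision,
       fusion = fus, segregation = seg)
}

#' The four printed audiovisual signal pairs of the simulation figure
#'
#' @return A tibble with columns `panel`, `xA`, `xV`.
#' @export
figure8_pairs <- function() {
  tibble::tibble(panel = c("a", "b", "c", "d"),
                 xA = c(-1.45, -1.23, -0.95, 0.23),
                 xV = c(2.20, 1.88, 1.76, 1.80))
}

# ---- vectorized inference core -------------------------------------------
# used by the simulator and the Monte-Carlo likelihood; closed-form only.

# audiovisual: returns p_c1 and the three category masses per row
.av_batch <- function(xA, xV, params) {
  sA2 <- params$sigma2_A; sV2 <- params$sigma2_V; L <- params$L
  pc <- params$p_common
  vf <- 1 / (1 / sA2 + 1 / sV2)
  mf <- (xA / sA2 + xV / sV2) * vf
  m1 <- stats::dnorm(xA - xV, 0, sqrt(sA2 + sV2)) / (2 * L) *
    (stats::pnorm((L - mf) / sqrt(vf)) - stats::pnorm((-L - mf) / sqrt(vf)))
  m2 <- .marginal_single(xA, sA2, L) * .marginal_single(xV, sV2, L)
  p1 <- if (pc == 1) rep(1, length(xA)) else if (pc == 0) rep(0, length(xA)) else
    pc * m1 / (pc * m1 + (1 - pc) * m2)
  cm <- .cat_mass_batch(mf, vf, params)
  sm <- .cat_mass_batch(xA, sA2, params)
  list(p_c1 = p1,
       bp = p1 * cm$bp + (1 - p1) * sm$bp,
       dt = p1 * cm$dt + (1 - p1) * sm$dt,
       gk = p1 * cm$gk + (1 - p1) * sm$gk)
}

# category masses of one truncated normal per row
.cat_mass_batch <- function(mean, var, params) {
  s <- sqrt(var)
  L <- params$L
  zlo <- stats::pnorm((-L - mean) / s)
  z <- stats::pnorm((L - mean) / s) - zlo
  plo <- (stats::pnorm((params$boundary_lo - mean) / s) - zlo) / z
  phi <- (stats::pnorm((params$boundary_hi - mean) / s) - zlo) / z
  list(bp = plo, dt = phi - plo, gk = 1 - phi)
}

# vectorized categorical decision + latent confidence from mass columns
.decide_batch <- function(bp, dt, gk, rule) {
  m <- cbind(bp, dt, gk)
  idx <- max.col(m, ties.method = "first")
  conf <- switch(rule,
    "chosen-posterior" = m[cbind(seq_len(nrow(m)), idx)],
    "neg-entropy" = {
      ml <- m * log(pmax(m, 1e-300))
      1 + rowSums(ml) / log(3)
    },
    "top-two-difference" = {
      mx <- m[cbind(seq_len(nrow(m)), idx)]
      m2 <- m; m2[cbind(seq_len(nrow(m)), idx)] <- -Inf
      mx - apply(m2, 1, max)
    })
  list(percept = PLACE_LEVELS[idx], confidence = conf)
}
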