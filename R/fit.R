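# Monte-Carlo response-probability table for one stimulus condition.
# zA, zV are standard-normal draws shared across parameter evaluations
# (common random numbers), so the likelihood surface is deterministic
# and smooth in the parameters given the seed.
.condition_response_probs <- function(muA, muV, modality, params, zA, zV) {
  floor_p <- 1e-12
  if (modality == "AV") {
    xA <- muA + sqrt(params$sigma2_A) * zA
    xV <- muV + sqrt(params$sigma2_V) * zV
    b <- .av_batch(xA, xV, params)
    dec <- .decide_batch(b$bp, b$dt, b$gk, params$confidence_rule)
    causal <- ifelse(b$p_c1 >= 0.5, "C=1", "C=2")
    cells <- table(factor(dec$percept, PLACE_LEVELS),
                   factor(causal, c("C=1", "C=2")))
    p <- cells / length(zA)
    lam <- params$lapse_rate
    a_av <- max(params$voicing_acc_A, params$voicing_acc_V)
    # P(consonant, causal) = (1-lam) P(place,causal) P(voicing) + lam/12
    out <- array(NA_real_, c(6, 2),
                 dimnames = list(CONSONANTS, c("C=1", "C=2")))
    for (cons in CONSONANTS) {
      pv <- c(voiced = a_av, unvoiced = 1 - a_av)
      for (k in c("C=1", "C=2"))
        out[cons, k] <- (1 - lam) * p[.place_of(cons), k] *
          unname(pv[.voicing_of(cons)]) + lam / 12
    }
    # pv above assumes the true voicing is 'voiced'; fixed up by caller
    pmax(out, floor_p)
  } else {
    sig2 <- if (modality == "A") params$sigma2_A else params$sigma2_V
    acc <- if (modality == "A") params$voicing_acc_A else params$voicing_acc_V
    mu <- if (modality == "A") muA else muV
    z <- if (modality == "A") zA else zV
    x <- mu + sqrt(sig2) * z
    m <- .cat_mass_batch(x, sig2, params)
    dec <- .decide_batch(m$bp, m$dt, m$gk, params$confidence_rule)
    p <- table(factor(dec$percept, PLACE_LEVELS)) / length(z)
    lam <- params$lapse_rate
    out <- stats::setNames(numeric(6), CONSONANTS)
    for (cons in CONSONANTS) {
      pv <- if (.voicing_of(cons) == "voiced") acc else 1 - acc
      out[cons] <- (1 - lam) * p[.place_of(cons)] * pv + lam / 6
    }
    pmax(out, floor_p)
  }
}

#' Monte-Carlo log-likelihood of a trial table under the observer model
#'
#' The likelihood is over the discrete joint response — consonant x causal
#' report on audiovisual trials, consonant alone on unisensory trials —
#' marginalized over the internal signals by Monte Carlo: standard-normal
#' draws are fixed by the seed and reused for every parameter value (common
#' random numbers), then scaled by the candidate noise parameters, pushed
#' through the observer, and tallied into response-cell probabilities per
#' stimulus condition. Lapses mix each cell with the uniform response
#' distribution (1/12 on audiovisual, 1/6 on unisensory trials). Confidence
#' reports are deliberately excluded: their mapping from latent confidence to
#' the report scale is a convention, not part of the model.
#'
#' Response probabilities are floored at 1e-12, so a response that the model
#' assigns zero probability (possible when `lapse_rate = 0`) contributes a
#' large but finite penalty; the result then carries attribute
#' `floored = TRUE`.
#'
#' @param trials a trial-record tibble (simulated or observed).
#' @param params an [observer_params()] to evaluate.
#' @param n_mc Monte-Carlo draws per stimulus condition (>= 1000 advised).
#' @param seed integer seed fixing the Monte-Carlo draws.
#' @return The summed log-likelihood (scalar), with attribute `floored`.
#' @export
trial_loglik <- function(trials, params, n_mc = 2000, seed = 1) {
  validate_observer_params(params)
  if (n_mc < 1) stop("n_mc must be positive")
  z <- with_seed_local(seed, list(zA = stats::rnorm(n_mc),
                                  zV = stats::rnorm(n_mc)))
  muA <- .coord_of(.place_of(trials$auditory_consonant))
  muV <- .coord_of(.place_of(trials$visual_consonant))
  key <- paste(trials$modality, muA, muV, trials$voicing)
  ll <- 0
  floored <- FALSE
  for (k in unique(key)) {
    idx <- which(key == k)
    i1 <- idx[1]
    probs <- .condition_response_probs(muA[i1], muV[i1], trials$modality[i1],
                                       params, z$zA, z$zV)
    true_voicing <- trials$voicing[i1]
    sub <- trials[idx, ]
    if (trials$modality[i1] == "AV") {
      # probs was built assuming a voiced stimulus; mirror voicing rows if not
      if (true_voicing == "unvoiced") {
        flip <- vapply(CONSONANTS, function(cn)
          unname(.consonant_of(.place_of(cn), .flip_voicing(.voicing_of(cn)))),
          character(1))
        probs <- probs[flip, , drop = FALSE]
        rownames(probs) <- CONSONANTS
      }
      p <- probs[cbind(sub$response_consonant, sub$causal_response)]
    } else {
      if (true_voicing == "unvoiced") {
        flip <- vapply(CONSONANTS, function(cn)
          unname(.consonant_of(.place_of(cn), .flip_voicing(.voicing_of(cn)))),
          character(1))
        probs <- probs[flip]
        names(probs) <- CONSONANTS
      }
      p <- probs[sub$response_consonant]
    }
    if (any(p <= 1.5e-12)) floored <- TRUE
    ll <- ll + sum(log(p))
  }
  structure(ll, floored = floored)
}

#' Fit observer parameters to a trial table by maximum likelihood
#'
#' Maximizes [trial_loglik()] over the noise variances and the causal prior
#' by bounded derivative-free search (Nelder–Mead on a logit-transformed
#' scale), with common random numbers across evaluations so the Monte-Carlo
#' surface is optimizable. All other observer parameters (support, category
#' boundaries, lapse rate, voicing accuracies, confidence rule) are held at
#' `base_params`.
#'
#' @param trials a trial-record tibble; an identifiable design includes both
#'   unisensory and audiovisual trials.
#' @param base_params an [observer_params()] providing the fixed fields.
#' @param init named initial values for `sigma2_A`, `sigma2_V`, `p_common`.
#' @param lower,upper named box bounds for the three free parameters.
#' @param n_mc Monte-Carlo draws per condition and evaluation.
#' @param seed integer seed (Monte-Carlo draws; the search is deterministic
#'   given the seed).
#' @param maxit maximum Nelder–Mead iterations.
#' @return A `fit_result` list: `estimates` (named vector), `loglik`,
#'   `converged`, `bounds`, `n_trials`, `n_mc`.
#' @export
fit_observer <- function(trials, base_params = observer_params(),
                         init = c(sigma2_A = 1, sigma2_V = 1, p_common = 0.5),
                         lower = c(sigma2_A = 0.05, sigma2_V = 0.05,
                                   p_common = 0.01),
                         upper = c(sigma2_A = 10, sigma2_V = 10,
                                   p_common = 0.99),
                         n_mc = 2000, seed = 1, maxit = 400) {
  free <- c("sigma2_A", "sigma2_V", "p_common")
  stopifnot(all(free %in% names(init)), all(free %in% names(lower)),
            all(free %in% names(upper)))
  to_theta <- function(p) stats::qlogis((p[free] - lower[free]) /
                                          (upper[free] - lower[free]))
  to_p <- function(theta) lower[free] +
    (upper[free] - lower[free]) * stats::plogis(theta)
  make_params <- function(p) {
    q <- base_params
    q$sigma2_A <- unname(p["sigma2_A"])
    q$sigma2_V <- unname(p["sigma2_V"])
    q$p_common <- unname(p["p_common"])
    q
  }
  nll <- function(theta) {
    p <- to_p(theta)
    -as.numeric(trial_loglik(trials, make_params(p), n_mc = n_mc, seed = seed))
  }
  opt <- stats::optim(to_theta(init), nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  est <- to_p(opt$par)
  structure(list(
    estimates = est,
    loglik = -opt$value,
    converged = opt$convergence == 0L,
    bounds = list(lower = lower, upper = upper),
    n_trials = nrow(trials),
    n_mc = n_mc
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Observer fit (Monte-Carlo maximum likelihood)\n")
  cat(sprintf("  sigma2_A = %.3f, sigma2_V = %.3f, p_common = %.3f\n",
              x$estimates["sigma2_A"], x$estimates["sigma2_V"],
              x$estimates["p_common"]))
  cat(sprintf("  log-likelihood %.2f over %d trials (n_mc %d); converged: %s\n",
              x$loglik, x$n_trials, x$n_mc, x$converged))
  invisible(x)
}
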