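# Independent numerical oracles: brute-force quadrature and pairwise
# counting, deliberately sharing no code with the closed-form implementation.

# trapezoid rule on a fixed grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# causal posterior by quadrature of the marginal likelihoods under the
# bounded-uniform prior
quad_causal_posterior <- function(xA, xV, params, n_grid = 20001) {
  s <- seq(-params$L, params$L, length.out = n_grid)
  u <- 1 / (2 * params$L)
  m1 <- trapz(s, u * dnorm(xA, s, sqrt(params$sigma2_A)) *
                dnorm(xV, s, sqrt(params$sigma2_V)))
  m2 <- trapz(s, u * dnorm(xA, s, sqrt(params$sigma2_A))) *
    trapz(s, u * dnorm(xV, s, sqrt(params$sigma2_V)))
  pc <- params$p_common
  pc * m1 / (pc * m1 + (1 - pc) * m2)
}

# category masses by quadrature of a density function over the three bins
quad_category <- function(dens, params, n_grid = 40001) {
  bins <- function(a, b) {
    s <- seq(a, b, length.out = n_grid)
    trapz(s, dens(s))
  }
  raw <- c(bins(-params$L, params$boundary_lo),
           bins(params$boundary_lo, params$boundary_hi),
           bins(params$boundary_hi, params$L))
  raw / sum(raw)
}

# full-path quadrature oracle: model-averaged category masses for one AV pair
quad_av_category <- function(xA, xV, params, n_grid = 40001) {
  p1 <- quad_causal_posterior(xA, xV, params, n_grid)
  rA <- 1 / params$sigma2_A
  rV <- 1 / params$sigma2_V
  mf <- (rA * xA + rV * xV) / (rA + rV)
  vf <- 1 / (rA + rV)
  tn <- function(m, v) {
    # truncated-normal density on [-L, L], normalized by quadrature
    function(s) {
      d <- dnorm(s, m, sqrt(v))
      g <- seq(-params$L, params$L, length.out = n_grid)
      d / trapz(g, dnorm(g, m, sqrt(v)))
    }
  }
  dens <- function(s) p1 * tn(mf, vf)(s) +
    (1 - p1) * tn(xA, params$sigma2_A)(s)
  list(p_c1 = p1, category = quad_category(dens, params, n_grid))
}

# O(n^2) pairwise-counting oracle for the confidence normalization
brute_normalize <- function(x) {
  vapply(x, function(xi) 0.5 * (mean(x < xi) + mean(x <= xi)), numeric(1))
}

default_params <- function(...) observer_params(...)

# a tiny hand-built normalized AV trial table for summary unit tests
make_toy_trials <- function() {
  tibble::tibble(
    subject = "S1",
    block = 1L, trial = 1:10, phase = "main",
    modality = "AV",
    condition = c(rep("AVc", 5), rep("McGurk", 5)),
    consonant = c("D", "D", "G", "G", "B", "B", "B", "B", "B", "B"),
    vowel = "a",
    place_class = c("D/T", "D/T", "G/K", "G/K", "B/P", rep("B/P", 5)),
    voicing = "voiced",
    mcgurk = c(rep(FALSE, 5), rep(TRUE, 5)),
    auditory_consonant = c("D", "D", "G", "G", "B", rep("B", 5)),
    visual_consonant = c("D", "D", "G", "G", "B", rep("G", 5)),
    percept_place = c("D/T", "D/T", "G/K", "B/P", "B/P",
                      "G/K", "G/K", "D/T", "D/T", "B/P"),
    percept_voicing = "voiced",
    response_consonant = c("D", "D", "G", "B", "B", "G", "G", "D", "D", "B"),
    perceptual_confidence_level = c(4L, 3L, 4L, 1L, 2L, 3L, 4L, 2L, 1L, 1L),
    causal_response = c("C=1", "C=1", "C=1", "C=2", "C=1",
                        "C=1", "C=1", "C=1", "C=2", "C=2"),
    causal_confidence_report = c(0.9, 0.8, 0.7, 0.2, 0.6,
                                 0.8, 0.9, 0.5, 0.3, 0.1),
    lapse = FALSE
  )
}

toy_normalized <- function() add_normalized_confidence(make_toy_trials())
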