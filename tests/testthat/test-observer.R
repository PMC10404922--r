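test_that("fusion is precision-weighted with reduced variance", {
  p <- observer_params()
  f <- fused_posterior(sensory_sample(-1.45, 2.20), p)
  expect_equal(f$mean, 0.375)
  expect_equal(f$var, 0.365)

  p2 <- observer_params(sigma2_A = 1.0, sigma2_V = 0.5)
  f2 <- fused_posterior(sensory_sample(0, 1.5), p2)
  expect_equal(f2$mean, 1.0)
  expect_equal(f2$var, 1 / 3)

  # convexity: identical signals fuse to themselves, whatever the variances
  set.seed(7)
  for (i in 1:20) {
    c0 <- runif(1, -2, 2)
    pi <- observer_params(sigma2_A = runif(1, 0.1, 3),
                          sigma2_V = runif(1, 0.1, 3))
    fi <- fused_posterior(sensory_sample(c0, c0), pi)
    expect_equal(fi$mean, c0)
    expect_lte(fi$var, min(pi$sigma2_A, pi$sigma2_V))
  }

  expect_error(fused_posterior(sensory_sample(xA = 1), p), "unisensory")
})

test_that("segregation returns the renormalized likelihood of one modality", {
  p <- observer_params()
  sa <- segregated_posterior(sensory_sample(xA = -1.45), p, "auditory")
  expect_equal(sa$mean, -1.45)
  expect_equal(sa$var, 0.73)
  sv <- segregated_posterior(sensory_sample(xV = 1.80), p, "visual")
  expect_equal(sv$mean, 1.80)
  expect_equal(sv$var, 0.73)
  expect_error(segregated_posterior(sensory_sample(xA = 1), p, "visual"),
               "unisensory mismatch")

  # signal at +L with small noise: truncated density still integrates to 1
  pn <- observer_params(sigma2_A = 0.04)
  comp <- segregated_posterior(sensory_sample(xA = pn$L), pn, "auditory")
  s <- seq(-pn$L, pn$L, length.out = 40001)
  expect_equal(trapz(s, posterior_density(comp, s)), 1, tolerance = 1e-8)
})

test_that("closed-form causal posterior matches the quadrature oracle", {
  p <- observer_params()
  expect_equal(causal_posterior(sensory_sample(0, 0), p), 0.6647410380,
               tolerance = 1e-8)
  expect_equal(causal_posterior(sensory_sample(-1.45, 2.20), p),
               0.0252925846, tolerance = 1e-7)
  set.seed(11)
  for (i in 1:25) {
    pi <- observer_params(sigma2_A = runif(1, 0.2, 2),
                          sigma2_V = runif(1, 0.2, 2),
                          p_common = runif(1, 0.05, 0.95),
                          L = runif(1, 2, 5))
    xA <- runif(1, -2.5, 2.5); xV <- runif(1, -2.5, 2.5)
    expect_equal(causal_posterior(sensory_sample(xA, xV), pi),
                 quad_causal_posterior(xA, xV, pi), tolerance = 1e-6)
  }
  # degenerate prior
  expect_identical(causal_posterior(sensory_sample(3, -3),
                                    observer_params(p_common = 1)), 1)
})

test_that("model averaging mixes fusion and segregation by the causal posterior", {
  p <- observer_params()
  s <- seq(-3, 3, length.out = 1001)

  mix <- model_average_posterior(sensory_sample(-1.45, 2.20), p)
  p1 <- attr(mix, "p_c1")
  # direct mixture oracle: weighted truncated-normal densities
  tn <- function(m, v) dnorm(s, m, sqrt(v)) /
    (pnorm((3 - m) / sqrt(v)) - pnorm((-3 - m) / sqrt(v)))
  direct <- p1 * tn(0.375, 0.365) + (1 - p1) * tn(-1.45, 0.73)
  expect_lt(max(abs(posterior_density(mix, s) - direct)), 1e-9)
  expect_equal(trapz(seq(-3, 3, length.out = 40001),
                     posterior_density(mix, seq(-3, 3, length.out = 40001))),
               1, tolerance = 1e-8)

  # boundary weights collapse the mixture onto one component
  m1 <- model_average_posterior(sensory_sample(0.2, 0.4),
                                observer_params(p_common = 1))
  f1 <- fused_posterior(sensory_sample(0.2, 0.4), p)
  expect_equal(posterior_density(m1, s), posterior_density(f1, s))
  m0 <- model_average_posterior(sensory_sample(0.2, 0.4),
                                observer_params(p_common = 0))
  s0 <- segregated_posterior(sensory_sample(0.2, 0.4), p, "auditory")
  expect_equal(posterior_density(m0, s), posterior_density(s0, s))
})

test_that("category posterior integrates the posterior between the boundaries", {
  p <- observer_params()
  fus <- fused_posterior(sensory_sample(-1.45, 2.20), p)
  cm <- category_posterior(fus, p)
  expect_equal(sum(cm), 1, tolerance = 1e-9)
  expect_equal(unname(cm), c(0.073766, 0.508195, 0.418039), tolerance = 1e-5)

  # full-path agreement with the quadrature oracle on the Fig 8a pair
  mix <- model_average_posterior(sensory_sample(-1.45, 2.20), p)
  oc <- quad_av_category(-1.45, 2.20, p)
  expect_equal(unname(category_posterior(mix, p)), oc$category,
               tolerance = 1e-6)

  # symmetric posterior with symmetric boundaries: equal outer masses
  # (the fused component of equally reliable, mirror-image signals)
  cs <- category_posterior(fused_posterior(sensory_sample(-0.8, 0.8), p), p)
  expect_equal(cs[["B/P"]], cs[["G/K"]], tolerance = 1e-12)

  expect_error(category_posterior(fus, observer_params(L = 3,
                                                       boundary_hi = 0.5,
                                                       boundary_lo = -0.5)),
               NA)
  pbad <- observer_params()
  pbad$boundary_hi <- 4
  expect_error(category_posterior(fus, pbad), "configuration error")
})

test_that("decisions and latent confidences follow the stated rules", {
  p <- observer_params()
  mk <- function(catp, p_c1 = NA_real_, post = NULL) {
    list(p_c1 = p_c1, posterior = post,
         category_posterior = setNames(catp, c("B/P", "D/T", "G/K")))
  }
  out <- decide_and_confide(mk(c(0.851, 0.130, 0.019), p_c1 = 0.0253), p)
  expect_identical(out$percept, "B/P")
  expect_equal(out$perceptual_confidence_latent, 0.851)
  expect_identical(out$causal_decision, "C=2")

  # maximal uncertainty under the two alternative readout rules
  u <- c(1, 1, 1) / 3
  pe <- observer_params(confidence_rule = "neg-entropy")
  post <- segregated_posterior(sensory_sample(xA = 0), p, "auditory")
  expect_equal(decide_and_confide(mk(u, post = post),
                                  pe)$perceptual_confidence_latent, 0,
               tolerance = 1e-12)
  pt <- observer_params(confidence_rule = "top-two-difference")
  expect_equal(decide_and_confide(mk(u, post = post),
                                  pt)$perceptual_confidence_latent, 0,
               tolerance = 1e-12)

  # threshold boundary: p_c1 = 0.5 resolves to C=1 with zero causal confidence
  out5 <- decide_and_confide(mk(c(0.2, 0.5, 0.3), p_c1 = 0.5), p)
  expect_identical(out5$causal_decision, "C=1")
  expect_equal(out5$causal_confidence_latent, 0)

  # exact category tie resolves to the category containing the posterior
  # mean (here 0, i.e. D/T); if the mean's class is not among the tied
  # maxima the first tied category wins
  tied <- decide_and_confide(mk(c(0.5, 0.5, 0), post = post), p)
  expect_identical(tied$percept, "D/T")
  tied2 <- decide_and_confide(mk(c(0.4, 0.2, 0.4), post = post), p)
  expect_identical(tied2$percept, "B/P")
})

test_that("figure panels reproduce the printed signal pairs coherently", {
  p <- observer_params()
  prs <- figure8_pairs()
  pc1 <- numeric(4)
  for (i in 1:4) {
    panel <- figure8_panel(prs$xA[i], prs$xV[i], p, grid_n = 201)
    expect_equal(sum(panel$category_posterior), 1, tolerance = 1e-9)
    pc1[i] <- panel$p_c1
  }
  # conflict |xA - xV| decreases a -> d, so p_c1 increases monotonically
  expect_true(all(diff(pc1) > 0))
  expect_equal(pc1, c(0.0252925846, 0.0751836654, 0.1484152620, 0.4807836795),
               tolerance = 1e-7)
})

test_that("structural invariants of the observer hold", {
  p <- observer_params()

  # p_c1 strictly decreasing in conflict at fixed midpoint
  mid <- 0.3
  conflict <- seq(0, 4, by = 0.25)
  pc1 <- vapply(conflict, function(d)
    causal_posterior(sensory_sample(mid - d / 2, mid + d / 2), p), numeric(1))
  expect_true(all(diff(pc1) < 0))

  # equal signals maximize p_c1 over pairs with the same midpoint
  d_grid <- seq(-3, 3, by = 0.1)
  pc_grid <- vapply(d_grid, function(d)
    causal_posterior(sensory_sample(mid - d / 2, mid + d / 2), p), numeric(1))
  expect_equal(d_grid[which.max(pc_grid)], 0)

  # sigma2_V -> infinity: fused mean -> xA
  pv <- observer_params(sigma2_V = 1e8)
  expect_equal(fused_posterior(sensory_sample(-0.7, 2.1), pv)$mean, -0.7,
               tolerance = 1e-6)

  # mirror symmetry: negating the axis swaps B/P and G/K exactly
  set.seed(5)
  for (i in 1:10) {
    xA <- runif(1, -2, 2); xV <- runif(1, -2, 2)
    pa <- observer_params(sA = -1, sV = 1, sigma2_A = runif(1, 0.3, 1.5),
                          sigma2_V = runif(1, 0.3, 1.5))
    pb <- observer_params(sA = 1, sV = -1, sigma2_A = pa$sigma2_A,
                          sigma2_V = pa$sigma2_V)
    ca <- category_posterior(model_average_posterior(sensory_sample(xA, xV), pa), pa)
    cb <- category_posterior(model_average_posterior(sensory_sample(-xA, -xV), pb), pb)
    expect_equal(unname(ca), rev(unname(cb)), tolerance = 1e-12)
    expect_equal(causal_posterior(sensory_sample(xA, xV), pa),
                 causal_posterior(sensory_sample(-xA, -xV), pb),
                 tolerance = 1e-12)
  }

  # unisensory inference reports causal quantities as absent, not zero
  uni <- infer_trial(sensory_sample(xA = 0.4), p)
  expect_true(is.na(uni$p_c1))
  expect_true(is.na(uni$causal_decision))
  expect_true(is.na(uni$causal_confidence_latent))
  expect_equal(sum(uni$category_posterior), 1, tolerance = 1e-9)
})

test_that("parameter validation rejects inconsistent configurations", {
  expect_error(observer_params(sigma2_A = 0), "sigma2_A")
  expect_error(observer_params(p_common = 1.2), "p_common")
  expect_error(observer_params(L = 0.4), "exceed both category boundaries")
  expect_error(observer_params(boundary_lo = 1, boundary_hi = -1),
               "boundary_lo")
  expect_error(observer_params(voicing_acc_V = 0.2), "voicing_acc_V")
  expect_error(sensory_sample(), "at least one")
  expect_error(sensory_sample(Inf, 0), "finite")
})
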