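#!/usr/bin/env Rscript
# Parameter recovery on synthetic data: fit the observer's noise variances
# and causal prior to one simulated session set (2,304 main trials) by
# Monte-Carlo maximum likelihood and compare with the generating values.

suppressPackageStartupMessages(library(mcgurkci))

true <- observer_params()
trials <- read_trials("results/trials_normalized.csv")
one <- trials[trials$subject == "S01" & trials$phase == "main", ]
cat("Fitting", nrow(one), "trials from subject S01...\n")
fit <- fit_observer(one, base_params = true, n_mc = 1500, seed = 1,
                    maxit = 300)
print(fit)
cat(sprintf("Generating values: sigma2_A = %.2f, sigma2_V = %.2f, p_common = %.2f\n",
            true$sigma2_A, true$sigma2_V, true$p_common))
jsonlite::write_json(
  list(estimates = as.list(fit$estimates), loglik = fit$loglik,
       converged = fit$converged, n_trials = fit$n_trials, n_mc = fit$n_mc,
       truth = list(sigma2_A = true$sigma2_A, sigma2_V = true$sigma2_V,
                    p_common = true$p_common)),
  "results/fit.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/fit.json\n")
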