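#!/usr/bin/env Rscript
# Confidence intervals and the two sensitivity analyses on the reduced
# compartmented fit: profile-likelihood CIs for the fitted parameters,
# mean normalized objective sensitivity (100 random 5% perturbations per
# parameter), and the response of the estimated fluxes to moving a
# measured rate to its confidence-interval border.

library(instcho)

dir.create("results/sensitivity", showWarnings = FALSE, recursive = TRUE)
mids <- read_mid_csv("results/synthetic/mids_corrected.csv")
dat <- mid_data(mids)

net <- load_network(cho_network_path("compartmented"))
scn <- cho_default_scenario(network = net)
red <- make_reduced_scenario(scn, 2)   # ppp and chan
fit <- global_fit(net, dat, params = red$params, fixed = red$fixed,
                  config = list(pop_factor = 10, generations = 10, seed = 1))
print(fit)

ci <- confidence_intervals(fit, n_steps = 8L, maxit = 20L)
write.csv(ci, "results/sensitivity/confidence_intervals.csv", row.names = FALSE)
print(ci, digits = 4)

sens_p <- sensitivity_of_objective(fit, n_perturb = 100L, seed = 1)
write.csv(data.frame(parameter = names(sens_p), sens_ssqd = sens_p),
          "results/sensitivity/objective_sensitivity.csv", row.names = FALSE)
cat("objective sensitivities (mean |dSSQD/SSQD| per |dp/p|):\n")
print(round(sens_p, 2))

# move the glucose uptake rate by +/-2% (a stand-in for its CI border)
glc <- net$measured$glc_upt$value
sens_m <- sensitivity_to_measured(
  fit, data.frame(rate = "glc_upt", lo = 0.98 * glc, hi = 1.02 * glc),
  net, maxit = 20L)
write.csv(data.frame(flux = rownames(sens_m), sens = sens_m[, 1]),
          "results/sensitivity/measured_rate_sensitivity.csv",
          row.names = FALSE)
cat("\nfluxes most sensitive to the glucose uptake rate:\n")
ord <- order(-abs(sens_m[, 1]))
print(round(sens_m[head(ord, 8), 1], 2))
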