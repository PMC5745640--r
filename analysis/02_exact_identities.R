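#!/usr/bin/env Rscript
# Exact (sampling-free) population analysis: the true causal effect of each
# scenario by do-calculus, the population limits of both estimators for
# every named strategy, and the scenario-1 identity chain over a grid of
# the two outcome-side effects.  Writes results/population_estimands.csv
# and results/scenario1_identities.csv.

suppressPackageStartupMessages(library(cequiv))
dir.create("results", showWarnings = FALSE)

tabs <- list()
for (sc in c("fig1a", "fig1b", "fig1c", "fig1d")) {
  m <- build_scenario(sc)
  sets <- unlist(scenario_strategies(m), recursive = FALSE)
  names(sets) <- sub("^[A-Z]\\.", "", names(sets))
  tab <- estimand_report(m, make_strategies(sets))
  tabs[[sc]] <- cbind(scenario = sc, tab)
}
est <- do.call(rbind, tabs)
write.csv(est, "results/population_estimands.csv", row.names = FALSE)
cat("Population values and asymptotic biases (default parameters):\n")
print(est, row.names = FALSE, digits = 4)

cat("\nIPW-MSM is exactly unbiased for every G-admissible set;",
    "every adjusted-logistic strategy carries a non-collapsibility bias.\n")

# Scenario-1 identity chain: beta^{T} = beta^{Z,T} = c3 always; the
# {Z}-adjusted coefficient coincides only when c2 = 0 or c3 = 0 and is
# attenuated toward zero otherwise.
grid <- expand.grid(c2 = c(0, 0.5, log(3)), c3 = c(-0.8, 0, 0.9))
idn <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  m <- build_scenario("fig1a", overrides = as.list(grid[i, ]))
  data.frame(c2 = grid$c2[i], c3 = grid$c3[i],
             true_ace = true_ace_log_or(m),
             beta_Z = population_adjusted_coefficient(m, "Z"),
             beta_T = population_adjusted_coefficient(m, "T"),
             beta_ZT = population_adjusted_coefficient(m, c("Z", "T")))
}))
write.csv(idn, "results/scenario1_identities.csv", row.names = FALSE)
cat("\nScenario-1 adjusted-coefficient identities over the (c2, c3) grid:\n")
print(idn, row.names = FALSE, digits = 4)
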