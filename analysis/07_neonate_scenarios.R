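#!/usr/bin/env Rscript
# Step 7 -- Predicted exposure in neonates (< 28 days old).
#
# No ontogeny data exist for MAO-A, the dominant clearance pathway, so two
# bounding assumptions are simulated: adult MAO-A activity per gram of liver
# at all ages ("none") and a slow maturation ("slow", the conservative case).
# CYP2D6 keeps its default fast ontogeny in both.
# Usage: Rscript analysis/07_neonate_scenarios.R [--seed <int>]

library(lactpbpk)
dir.create("results", showWarnings = FALSE)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 101

cal <- calibrate_adult()
mother <- run_trial_set(scenario_mother_lactation(cal, seed = seed))
infant <- run_trial_set(scenario_infant(cal, seed = seed + 1))
rel_inf <- relative_exposure(infant, mother)[["cmax_pct"]]
cat(sprintf("infant (>=28 d) relative Cmax: %.3f%%\n", rel_inf))

for (maoa in c("maoa_none", "maoa_slow")) {
  res <- run_scenario(scenario_neonate(cal, maoa = maoa, seed = seed + 2),
                      "results")
  rel <- relative_exposure(res$summary, mother)
  cat(sprintf("neonate %-10s relative Cmax %.3f%%, AUC %.3f%% (max conc %.3f ng/mL)\n",
              sub("maoa_", "", maoa), rel[["cmax_pct"]], rel[["auc_pct"]],
              max(res$summary$subjects$cmax_all)))
}
cat("expected ordering: neonate slow > neonate none > infant\n")
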