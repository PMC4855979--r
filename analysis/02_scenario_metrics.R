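#!/usr/bin/env Rscript
# Step 2: single-run metrics for scenarios 1-6.
#
# Runs the full pipeline (simulate -> adjust -> test -> score) once per
# scenario at desk scale (20,000 probes, 46 individuals, S = 500 DMSs)
# with the unadjusted analysis and the four in-package adjustment methods,
# and writes the Table-3-shaped scorecard for each scenario.

library(cellmixsim)

dir.create("results", showWarnings = FALSE)
base <- generate_base_profiles(base_profile_config(
  n_probes = 20000, n_individuals = 46, seed = 2026
))
methods <- c("unadjusted", "refbased", "reffree", "sva", "ruv")

all <- list()
for (i in 1:6) {
  sc <- scenario_preset(i, seed = 100 + i)
  out <- run_pipeline(sc, base = base, methods = methods)
  all[[i]] <- out$metrics
  cat(sprintf("\nScenario %d (%s):\n", i, sc$name))
  print(out$metrics[, c("method", "nfp", "power", "ks", "gif", "K_hat")],
        row.names = FALSE)
}
metrics <- do.call(rbind, all)
write.table(metrics, "results/scenario_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

un <- metrics[metrics$method == "unadjusted", ]
cat("\nUnadjusted GIF across scenarios: ",
    paste(sprintf("%s=%.2f", un$scenario, un$gif), collapse = ", "), "\n")
cat("Confounded scenarios inflate the unadjusted analysis; reference-based\n")
cat("and SVA adjustment pull the GIF back toward 1.\n")
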