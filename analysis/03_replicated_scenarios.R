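#!/usr/bin/env Rscript
# Step 3: replicated runs for the few-DMS and many-correlated-DMS designs.
#
# Scenarios 7 (50 strong DMSs) and 8 (10,000 weak DMSs in two correlated
# blocks) are replicated ten times each — the DMS set, phenotype, effects
# and proportions are redrawn per replication — and the per-replication
# metrics are summarized as medians with interquartile ranges (the box-plot
# shape of the replicated comparisons).

library(cellmixsim)

dir.create("results", showWarnings = FALSE)
base <- generate_base_profiles(base_profile_config(
  n_probes = 20000, n_individuals = 46, seed = 2026
))
methods <- c("unadjusted", "refbased", "reffree", "sva", "ruv")

for (i in 7:8) {
  sc <- scenario_preset(i, seed = 100 + i)
  out <- run_pipeline(sc, base = base, methods = methods)
  write.table(out$metrics, sprintf("results/scenario%d_replications.tsv", i),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarize_replications(out$metrics)
  write.table(summ, sprintf("results/scenario%d_summary.tsv", i),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\nScenario %d (%s), %d replications — median [IQR] per method:\n",
              i, sc$name, sc$n_replications))
  g <- summ[summ$metric == "gif", ]
  n <- summ[summ$metric == "nfp", ]
  for (m in unique(g$method)) {
    cat(sprintf("  %-10s GIF %.2f [%.2f, %.2f]   NFP %g [%g, %g]\n", m,
                g$median[g$method == m], g$q1[g$method == m], g$q3[g$method == m],
                n$median[n$method == m], n$q1[n$method == m], n$q3[n$method == m]))
  }
}
cat("\nFew-DMS design: reference-based and SVA give the most consistent\n")
cat("false-positive control; the reference-free bootstrap stays inflated.\n")
cat("Many-DMS design at desk scale (half the probe universe is a DMS, far\n")
cat("denser than on a full array): reference-based and RUV remain calibrated,\n")
cat("while SVA cannot separate the genome-wide shift from the confounder and\n")
cat("the reference-free bootstrap over-corrects severely.\n")
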