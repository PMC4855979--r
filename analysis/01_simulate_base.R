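#!/usr/bin/env Rscript
# Step 1: generate the synthetic cell-separated base data and describe it.
#
# Emulates two-cell-type (monocyte / CD4+ T cell) sorted 450K beta values
# for 46 individuals: bimodal probe means, ~20% of probes strongly
# cell-type-differential, logit-scale individual noise, and 10 latent
# batch-like factors so that even sorted cells carry a latent dimension
# well above the two mixed cell types.

library(cellmixsim)

dir.create("results", showWarnings = FALSE)
cfg <- base_profile_config(n_probes = 20000, n_individuals = 46,
                           n_latent_factors = 10, seed = 2026)
base <- generate_base_profiles(cfg)

k1 <- estimate_latent_dim_rmt(base$beta[[1]])
k2 <- estimate_latent_dim_rmt(base$beta[[2]])

summary <- data.frame(
  n_probes = length(base$probe_ids),
  n_individuals = length(base$sample_ids),
  frac_differential = mean(base$differential_probe_mask),
  mean_beta_celltype1 = mean(base$beta[[1]]),
  mean_beta_celltype2 = mean(base$beta[[2]]),
  rmt_dim_celltype1 = k1,
  rmt_dim_celltype2 = k2
)
write.table(summary, "results/base_data_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Base data: %d probes x %d individuals, %.1f%% cell-type-differential.\n",
            summary$n_probes, summary$n_individuals, 100 * summary$frac_differential))
cat(sprintf("RMT latent dimension of the sorted matrices: %d (monocytes), %d (T cells)\n",
            k1, k2))
cat("-> even cell-separated data shows a latent dimension near the number of\n")
cat("   simulated batch-like factors, not the number of cell types.\n")
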