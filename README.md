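# cellmixsim

Simulation and adjustment of cell-type-mixture confounding in methylation
association studies.

## The problem

Epigenome-wide association studies (EWAS) measure DNA methylation in mixed
tissue (typically whole blood) while methylation differs sharply between the
constituent cell types. When cell-type composition also varies with the
phenotype, every cell-type-differential probe becomes spuriously associated
with it. `cellmixsim` is for methodologists and analysts who want to study
this mechanism quantitatively: it simulates the confounding from first
principles, adjusts for it with the standard method families, and scores
each method against the known truth.

## The model

Starting from cell-separated beta values β<sub>ijk</sub> (individual *i*,
probe *j*, cell type *k* ∈ {monocyte, T cell}), one run:

1. selects *S* differentially methylated sites (DMSs);
2. draws a phenotype z<sub>i</sub> ~ Bernoulli(0.5) or N(0,1);
3. leaves non-DMS probes untouched;
4. at DMSs draws hierarchical effects μ<sub>jk</sub> ~ N(μ<sub>k</sub>, σ<sub>k</sub>²),
   e<sub>ijk</sub> ~ N(μ<sub>jk</sub>, σ<sub>jk</sub>²) and sets
   β′<sub>ijk</sub> = logit⁻¹(logit(β<sub>ijk</sub>) + z<sub>i</sub> e<sub>ijk</sub>);
5. mixes the cell types with Dirichlet proportions whose expectation shifts
   with the phenotype:
   p<sub>i</sub> ~ Dirichlet(ρ·(α⁽⁰⁾ + z<sub>i</sub> Δα)),
   β<sup>f</sup><sub>ij</sub> = p<sub>i1</sub>β′<sub>ij1</sub> + p<sub>i2</sub>β′<sub>ij2</sub>.

Eight preset scenarios (shipped as YAML under `inst/extdata/scenarios/`)
vary the effect distributions, the Dirichlet precision ρ, the phenotype
type, and the DMS count — including a 50-DMS design and a 10,000-DMS design
with block-correlated effects, both replicated ten times.

Adjustment methods implemented in-package: **reference-based** (constrained
least squares against an independent sorted-cell panel), **reference-free**
(SVD of the concatenated coefficient and residual matrices, bootstrap
standard errors), **SVA** (permutation-based dimension choice plus
iteratively re-weighted SVD), and **RUV-4** (factors from negative-control
probes, K = 3). Probe-wise association tests use OLS with empirical-Bayes
variance moderation and a fixed significance threshold of 10⁻⁴. Methods are
scored by the number of false positives (NFP), power, the
Kolmogorov–Smirnov distance of the p values from uniform, and the genomic
inflation factor (GIF, the origin-constrained slope of the −log₁₀ p QQ
plot with true DMSs removed).

## Worked example

```r
library(cellmixsim)

base <- generate_base_profiles(base_profile_config(n_probes = 5000, seed = 42))
sc <- scenario_preset(1)       # distinct effect distributions, confounded
sc$S <- 100L
out <- run_pipeline(sc, base = base,
                    methods = c("unadjusted", "refbased", "sva", "ruv"),
                    n_controls = 400)
out$metrics[, c("method", "nfp", "power", "ks", "gif", "K_hat")]
```

```
      method nfp power         ks       gif K_hat
1 unadjusted  26  0.13 0.08262398 1.4987221    NA
2   refbased   0  0.09 0.01050825 0.9876116    NA
3        sva   2  0.08 0.00685639 1.0175698    11
4        ruv   0  0.09 0.01723241 1.0316700     3
```

The unadjusted analysis is inflated (GIF ≈ 1.5, 26 false positives among
4,900 null probes) because cases carry systematically more monocytes than
controls; reference-based and SVA adjustment restore calibration (GIF ≈ 1)
at a small cost in power, mirroring the qualitative ranking seen on real
sorted-cell data. The `analysis/` directory contains numbered drivers that
run the full study: base-data generation with latent-dimension checks
(`01`), single runs of scenarios 1–6 (`02`), ten replications of the
few-DMS and many-correlated-DMS designs (`03`), and QQ-table export (`04`);
each writes its tables under `results/`.

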