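---
title: "Simulating and adjusting cell-type-mixture confounding in methylation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and adjusting cell-type-mixture confounding in methylation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmixsim)
```

## The problem

Epigenome-wide association studies (EWAS) usually measure DNA methylation in
mixed tissue — most often whole blood — while methylation differs strongly
between the constituent cell types. If the cell-type composition of a sample
also varies with the phenotype under study, every probe that distinguishes
cell types becomes spuriously associated with the phenotype. This package
implements a multi-layer simulation of exactly this confounding mechanism
for a two-cell-type mixture (monocytes and CD4+ T cells), four standard
families of adjustment methods, probe-wise moderated association testing,
and the calibration metrics used to compare them.

## The simulation model

The generative model has two layers: a *base* layer emulating cell-sorted,
450K-like beta values, and a *mixing* layer that injects phenotype effects
and combines the cell types.

### Base layer

For probe $j$ and cell type $k$, a logit-scale mean is drawn from a
three-component normal mixture whose defaults concentrate near
$\mathrm{logit}(0.1)$ and $\mathrm{logit}(0.9)$ with a broad middle
component — the canonical bimodal shape of Illumina 450K beta values. A
fraction of probes (default 0.2) is cell-type-differential: the cell-type-2
logit mean is shifted by at least 1.5 logit units with random sign. The
defaults reflect sorted-blood comparisons, where a large minority of array
probes show substantial monocyte-versus-T-cell differences; since no public
summary pins down the exact probe-mean distribution of sorted SARD data,
these mixture defaults are tunable rather than calibrated. Individual
values add logit-scale noise ($\sigma = 0.3$) and, optionally, latent
batch-like factors shared across cell types with cell-type-specific
loadings:
$$\beta_{ijk} = \mathrm{logit}^{-1}\!\left(m_{jk} + \textstyle\sum_l
\lambda_{jlk} f_{il} + \varepsilon_{ijk}\right).$$
The latent factors reproduce a documented feature of real sorted data:
dimension estimates on cell-separated matrices are far larger than the
number of cell types, because subtler lineage and batch structure survives
sorting. With ten factors the random-matrix estimator below reports a
latent dimension of about ten on a single cell type's matrix
(`analysis/01_simulate_base.R`).

All logits are clipped so betas stay in $[10^{-6}, 1-10^{-6}]$; downstream
logit transforms require the open interval.

### Mixing layer

A scenario is parameterized by Table-style quantities: the DMS count $S$,
per-cell-type effect means and sds $(\mu_k, \sigma_k)$, the
individual-level sd $\sigma_{jk}$ (scalar or a $\mathrm{Unif}(0.1,2)$ range
realized once per probe and cell type per replication), the Dirichlet
precision $\rho$, baseline proportions $\alpha^{(0)}$, and the
per-unit-phenotype shift $\Delta\alpha$. One replication proceeds:

1. draw $S$ DMS probes uniformly without replacement;
2. draw the phenotype $z_i$ — Bernoulli(0.5) or standard normal;
3. pass non-DMS probes through unchanged;
4. at DMS probes, draw $\mu_{jk} \sim N(\mu_k, \sigma_k^2)$, then
   $e_{ijk} \sim N(\mu_{jk}, \sigma_{jk}^2)$, and set
   $\beta'_{ijk} = \mathrm{logit}^{-1}(\mathrm{logit}(\beta_{ijk}) + z_i e_{ijk})$;
5. draw proportions $p_i \sim \mathrm{Dirichlet}(\rho\,\alpha^{(z_i)})$ with
   $\alpha^{(z)} = \alpha^{(0)} + z\,\Delta\alpha$ and mix:
   $\beta^f_{ij} = p_{i1}\beta'_{ij1} + p_{i2}\beta'_{ij2}$.

Eight presets cover the study designs: distinct effect distributions,
equal effects, opposite effects, high/low Dirichlet precision
($\rho = 200/10$), a continuous phenotype ($\Delta\alpha = 0.03$), 50
strong DMSs, and 10,000 weak DMSs in two blocks of 5,000 whose effect
means are equicorrelated within block (correlations 0.4 and 0.5). The
block covariance is equicorrelation on each cell type's mean vector —
the design states only a fixed background correlation per block, and
cell types are never correlated with each other because the
parameterization is per-cell-type. For the blocked preset the top-level
$(\mu_k, \sigma_k)$ are block-averaged placeholders; the block entries
are authoritative.

Three boundary choices the model itself does not determine:

- Extreme continuous phenotypes can push $\alpha^{(z)}$ off the simplex;
  components are clipped at $10^{-6}$ and renormalized so the Dirichlet
  parameters stay positive. No truncation is applied to continuous $z$.
- The binary phenotype is drawn per replication, not balanced by design
  (Bernoulli(0.5) exactly).
- Each replication redraws the DMS set, phenotype, effects, proportions
  and any ranged $\sigma_{jk}$.

Every stochastic stage consumes its own seed derived from the master seed
by `stage_seed()` (a deterministic hash of stage label and replication
index), so any stage can be reproduced in isolation and results do not
depend on the order in which methods run.

## Adjustment methods

All four methods are implemented in this package and emit an `n × K`
covariate matrix for the downstream test. Input scales follow each
method's convention: beta values for reference-based and reference-free,
M-values (logit beta) for SVA and RUV; both are configurable.

**Reference-based.** Per-sample constrained least squares of the mixed
values on mean reference profiles from an independent sorted-cell cohort,
over the 100 probes with the largest absolute reference difference, under
$p_k \ge 0$, $\sum_k p_k = 1$. The sum-to-one constraint is appropriate
for a two-cell-type mixture and can be relaxed to $\le 1$ for incomplete
panels. The small exact active-set solver enumerates zero-sets, which is
exact for small $K$. The estimated first proportion is the adjustment
covariate.

**Reference-free.** The unadjusted probe-wise model's coefficient matrix
and residual matrix are concatenated column-wise and decomposed by SVD;
the leading probe-space singular vectors define latent directions, and
samples are scored by projecting the *centered data* (not the design
residuals) onto them, so latent variation correlated with the phenotype is
retained in the covariates. $K$ defaults to the random-matrix estimate on
the residual matrix. Standard errors come from a 100-resample bootstrap in
which the components are re-estimated within each resample.

**SVA.** The number of surrogate variables is chosen by a permutation test
on residual-matrix eigenvalue shares: each permutation scrambles every
probe's values independently and re-residualizes against the design, so
observed and permuted spectra share the same residual rank (without the
re-residualization the rank mismatch systematically inflates the observed
shares and hence $\hat K$). Surrogates are then refined by iteratively
re-weighted SVD with posterior-probability weights
$(1 - \mathrm{lfdr}(p_\gamma)) \cdot \mathrm{lfdr}(p_z)$ — strongly
associated with the current surrogates, not with the phenotype. The local
FDR is a Storey-type estimate (null proportion at $\lambda = 0.8$, kernel
density on the logit scale, monotonized). Raw p-value weights were
considered and rejected: on null probes they are Uniform(0,1) and inject
weight noise that measurably degrades confounder recovery; the lfdr
weights reproduce the recovery of the reference implementation in the
`sva` package (cross-checked in the test suite).

**RUV-4.** Negative-control probes are cell-type-differential probes
outside the DMS set that are not significantly correlated with the
phenotype (correlation-test screen at the 1% level; a fixed correlation
cutoff is also available). Factor loadings are estimated by SVD on the
design-orthogonal part of the control submatrix — so the primary effect
cannot leak into them — and the factors are then scored on the centered,
unprojected controls, retaining unwanted variation that is correlated
with the phenotype. $K$ is fixed at 3 by default, the setting used for
all reported comparisons; the random-matrix estimate on the controls is
logged as a diagnostic.

**Latent dimension.** `estimate_latent_dim_rmt()` standardizes each probe,
forms the sample correlation matrix, and counts eigenvalues above the
Marchenko–Pastur bulk edge $(1 + \sqrt{n/J})^2$.

Other published adjusters (ISVA, EWASher, Deconf, CellCDec) are reachable
only through the plug-in adapter — a TSV covariate matrix produced by any
external tool — and are deliberately not reimplemented; a failing plug-in
is isolated with a warning rather than aborting the run.

## Association testing and metrics

Each probe is tested by OLS on a shared design (intercept, phenotype,
adjustment covariates); the phenotype coefficient's variance is moderated
by the standard empirical-Bayes hierarchical model: a scaled inverse
chi-square prior $(d_0, s_0^2)$ estimated by method of moments on
$\log s^2$ (with a Newton trigamma inversion), posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and a moderated t on
$d_0 + d$ degrees of freedom. Tests default to beta values, matching the
simulator's output scale; an M-value option is exposed. P values are
two-sided; probes are significant when $p < 10^{-4}$ strictly. Probes
with numerically zero residual variance are resolved exactly (zero
coefficient gives $p = 1$, non-zero gives $p \to 0$).

Four metrics summarize each method against the simulation truth:

- **NFP** — non-DMS probes with $p < 10^{-4}$;
- **power** — fraction of DMS probes below the threshold;
- **KS** — supremum distance of the p-value ECDF from Uniform(0,1), used
  descriptively, not inferentially, because probe-wise tests are
  dependent; computed on non-DMS probes to match the GIF exclusion (a
  flag includes all probes);
- **GIF** — the least-squares-through-the-origin slope of observed vs
  expected $-\log_{10} p$ QQ points at plotting positions $(i-0.5)/m$,
  after excluding the true DMSs. This follows the QQ-slope definition of
  inflation; the median-chi-square $\lambda$ is available as an
  alternative for cross-checking.

## What the tests show — and what they do not

The test suite and analysis scripts work at desk scale: 1,000–20,000
probes and 10–46 individuals, chosen so that a full five-method scenario
run completes in seconds to a few minutes on one CPU; the shipped analysis
drivers use 20,000 probes and 46 individuals. Calibration targets (the
control-group mean proportion 0.57, the case-control difference 0.08, the
null GIF of 1.0) are recovered within Monte-Carlo error, and the headline
directional result reproduces: under a confounded scenario the unadjusted
GIF exceeds 1.2 and both reference-based and SVA adjustment pull it back
toward 1.

The generator emulates marginal and cell-type-differential structure of
sorted 450K data, not the arrays themselves: no Infinium type-I/type-II
chemistry, no normalization artifacts, no SNP or sex-chromosome probes,
no spatial/batch chip layout, and only two cell types. Passing tests
therefore demonstrate correctness of the machinery and qualitative
reproduction of the confounding phenomenon, not quantitative agreement
with any particular real cohort. One concrete divergence: in the
"no-confounding" preset (equal DMS effect distributions in the two cell
types) the phenotype still shifts mixture proportions, so with this
generator's strong cell-type-differential fraction the *unadjusted*
analysis remains inflated at non-DMS probes; truly unconfounded
calibration is checked with $\Delta\alpha = 0$ instead. Likewise, the
blocked many-DMS preset keeps the study's absolute size ($S = 10{,}000$),
which at the 20,000-probe desk scale makes half the universe a DMS —
far denser than on a 375k-probe array. In that regime the latent-variable
methods degrade (the reference-free bootstrap over-corrects, SVA cannot
separate the genome-wide shift from the confounder), while
reference-based and RUV adjustment remain calibrated
(`analysis/03_replicated_scenarios.R`).

## Known limitations

- The simplex solver enumerates active sets and is intended for small
  numbers of cell types (here, two).
- The SVA permutation test defaults to 100 permutations and a 0.05
  eigenvalue significance level; these counts are conventions, not
  estimates.
- Bootstrap standard errors for the reference-free method use a normal
  approximation on 100 resamples.
- The blocked (scenario-8) covariance couples probes within a block by
  simple equicorrelation; richer dependence (e.g. distance-decaying
  correlation along the genome) is out of scope.
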