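#' Configuration for the synthetic cell-separated base data
#'
#' Describes the statistical structure of cell-sorted, 450K-like methylation
#' beta values for two cell types (monocytes and CD4+ T cells in the study
#' design this emulates): a bimodal distribution of probe means, a subset of
#' probes strongly differential between the two cell types, logit-scale
#' inter-individual noise, and optional latent (batch-like) factors that give
#' even sorted cells a latent dimension well above the number of cell types.
#'
#' @param n_individuals number of individuals (the study design uses 46).
#' @param n_probes number of probes; the full array after filtering has
#'   375,639, the default 20,000 is a desk-scale subsample.
#' @param frac_celltype_differential fraction of probes in `[0,1]` whose two
#'   cell-type means differ by at least `min_differential_shift` on the
#'   logit scale.
#' @param min_differential_shift minimum absolute logit-scale difference
#'   between cell-type means at a differential probe.
#' @param probe_mean_mixture three-component normal mixture on the logit
#'   scale for probe-level mean methylation: list with `weights`, `means`,
#'   `sds`. The default places mass near beta = 0.1 and 0.9 with a broad
#'   middle component, the canonical bimodal shape of 450K beta values.
#' @param individual_sd_logit standard deviation of individual-level
#'   logit-scale noise around the probe/cell-type mean.
#' @param n_latent_factors number of latent factors (>= 0) shared across
#'   cell types, with cell-type-specific loadings.
#' @param latent_factor_sd standard deviation of latent-factor loadings on
#'   the logit scale.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return an object of class `base_profile_config`.
#' @export
base_profile_config <- function(n_individuals = 46L,
                                n_probes = 20000L,
                                frac_celltype_differential = 0.2,
                                min_differential_shift = 1.5,
                                probe_mean_mixture = list(
                                  weights = c(0.4, 0.2, 0.4),
                                  means = c(-2.2, 0, 2.2),
                                  sds = c(0.8, 1.2, 0.8)
                                ),
                                individual_sd_logit = 0.3,
                                n_latent_factors = 0L,
                                latent_factor_sd = 0.5,
                                seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 1 ||
      !is.numeric(n_probes) || n_probes < 1) {
    stop("n_individuals and n_probes must be positive counts", call. = FALSE)
  }
  if (frac_celltype_differential < 0 || frac_celltype_differential > 1) {
    stop("frac_celltype_differential must lie in [0, 1]", call. = FALSE)
  }
  if (min_differential_shift < 0) {
    stop("min_differential_shift must be non-negative", call. = FALSE)
  }
  w <- probe_mean_mixture$weights
  if (length(w) != length(probe_mean_mixture$means) ||
      length(w) != length(probe_mean_mixture$sds) ||
      any(w < 0) || sum(w) <= 0 || any(probe_mean_mixture$sds <= 0)) {
    stop("probe_mean_mixture needs matching weights/means/sds with sds > 0",
         call. = FALSE)
  }
  if (individual_sd_logit < 0) stop("individual_sd_logit must be >= 0", call. = FALSE)
  if (n_latent_factors < 0) stop("n_latent_factors must be >= 0", call. = FALSE)
  if (latent_factor_sd <= 0) stop("latent_factor_sd must be > 0", call. = FALSE)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_probes = as.integer(n_probes),
    frac_celltype_differential = frac_celltype_differential,
    probe_mean_mixture = lapply(probe_mean_mixture, as.numeric),
    min_differential_shift = min_differential_shift,
    individual_sd_logit = individual_sd_logit,
    n_latent_factors = as.integer(n_latent_factors),
    latent_factor_sd = latent_factor_sd,
    seed = as.integer(seed)
  ), class = "base_profile_config")
}

#' Generate cell-separated beta-value matrices for two cell types
#'
#' Draws per-probe logit-scale means from the configured bimodal mixture,
#' shifts a random fraction of probes in cell type 2 by at least
#' `min_differential_shift` (random sign), adds shared latent-factor
#' structure and individual-level normal noise on the logit scale, and maps
#' back to beta values clipped to the open unit interval.
#'
#' @param config a [base_profile_config()].
#' @return an object of class `cell_profile_pair`: list with `probe_ids`,
#'   `sample_ids`, `beta` (list of two `n_probes x n_individuals` matrices),
#'   `differential_probe_mask`, and the per-cell-type logit means in
#'   `logit_means` (an `n_probes x 2` matrix).
#' @export
generate_base_profiles <- function(config) {
  stopifnot(inherits(config, "base_profile_config"))
  J <- config$n_probes
  n <- config$n_individuals
  set.seed(stage_seed(config$seed, "base"))

  mix <- config$probe_mean_mixture
  comp <- sample.int(length(mix$weights), J, replace = TRUE,
                     prob = mix$weights / sum(mix$weights))
  m1 <- stats::rnorm(J, mean = mix$means[comp], sd = mix$sds[comp])

  n_diff <- round(config$frac_celltype_differential * J)
  mask <- rep(FALSE, J)
  if (n_diff > 0) mask[sample.int(J, n_diff)] <- TRUE
  shift <- numeric(J)
  if (n_diff > 0) {
    magnitude <- config$min_differential_shift + stats::rexp(n_diff, rate = 2)
    shift[mask] <- magnitude * sample(c(-1, 1), n_diff, replace = TRUE)
  }
  m2 <- m1 + shift
  logit_means <- cbind(celltype1 = m1, celltype2 = m2)

  # Latent factors: one score per individual, shared across cell types;
  # loadings are probe- and cell-type-specific.
  L <- config$n_latent_factors
  scores <- if (L > 0) matrix(stats::rnorm(L * n), nrow = L) else NULL

  beta <- vector("list", 2L)
  for (k in 1:2) {
    lg <- matrix(logit_means[, k], nrow = J, ncol = n)
    if (L > 0) {
      loadings <- matrix(stats::rnorm(J * L, sd = config$latent_factor_sd), nrow = J)
      lg <- lg + loadings %*% scores
    }
    if (config$individual_sd_logit > 0) {
      lg <- lg + matrix(stats::rnorm(J * n, sd = config$individual_sd_logit), nrow = J)
    }
    beta[[k]] <- clip_beta(inv_logit(lg))
  }

  probe_ids <- sprintf("cg%07d", seq_len(J))
  sample_ids <- sprintf("S%03d", seq_len(n))
  for (k in 1:2) dimnames(beta[[k]]) <- list(probe_ids, sample_ids)

  structure(list(
    probe_ids = probe_ids,
    sample_ids = sample_ids,
    beta = beta,
    differential_probe_mask = mask,
    logit_means = logit_means,
    config = config
  ), class = "cell_profile_pair")
}

#' Draw a new cohort from an existing base-profile population
#'
#' Keeps the population-level probe structure (probe means, cell-type
#' differential shifts, latent-factor loadings distribution) of an existing
#' `cell_profile_pair` and draws a fresh set of individuals — a biological
#' replicate cohort, as used for an external reference panel of sorted
#' cells.
#'
#' @param base a `cell_profile_pair` from [generate_base_profiles()].
#' @param n_individuals cohort size (defaults to the base cohort size).
#' @param seed integer seed.
#' @return a new `cell_profile_pair` sharing `probe_ids`,
#'   `differential_probe_mask` and `logit_means` with `base`.
#' @export
resample_cohort <- function(base, n_individuals = NULL, seed = 1L) {
  stopifnot(inherits(base, "cell_profile_pair"))
  config <- base$config
  if (is.null(config)) stop("base pair carries no generating config", call. = FALSE)
  n <- as.integer(n_individuals %||% config$n_individuals)
  J <- length(base$probe_ids)
  set.seed(stage_seed(seed, "cohort"))
  L <- config$n_latent_factors
  scores <- if (L > 0) matrix(stats::rnorm(L * n), nrow = L) else NULL
  beta <- vector("list", 2L)
  for (k in 1:2) {
    lg <- matrix(base$logit_means[, k], nrow = J, ncol = n)
    if (L > 0) {
      loadings <- matrix(stats::rnorm(J * L, sd = config$latent_factor_sd), nrow = J)
      lg <- lg + loadings %*% scores
    }
    if (config$individual_sd_logit > 0) {
      lg <- lg + matrix(stats::rnorm(J * n, sd = config$individual_sd_logit), nrow = J)
    }
    beta[[k]] <- clip_beta(inv_logit(lg))
  }
  sample_ids <- sprintf("R%03d", seq_len(n))
  for (k in 1:2) dimnames(beta[[k]]) <- list(base$probe_ids, sample_ids)
  structure(list(
    probe_ids = base$probe_ids,
    sample_ids = sample_ids,
    beta = beta,
    differential_probe_mask = base$differential_probe_mask,
    logit_means = base$logit_means,
    config = config
  ), class = "cell_profile_pair")
}

#' Write a beta-value matrix as tab-delimited text
#'
#' Probes as rows with a leading `probe_id` column, one named column per
#' sample, full numeric precision.
#'
#' @param beta numeric matrix with probe and sample dimnames, values in `[0,1]`.
#' @param path output file path.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]", call. = FALSE)
  # %.17g guarantees a bit-exact double round-trip through decimal text
  chr <- matrix(sprintf("%.17g", beta), nrow(beta))
  df <- data.frame(probe_id = rownames(beta), chr, check.names = FALSE)
  names(df)[-1] <- colnames(beta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-value matrix from delimited text
#'
#' Expects probes as rows with an ID column and samples as named columns.
#' Values outside `[0,1]`, non-numeric cells, ragged rows and duplicate
#' probe IDs are rejected.
#'
#' @param path file path (tab- or comma-delimited; inferred from content).
#' @return numeric matrix with probe IDs as rownames, samples as colnames.
#' @export
read_beta_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stop("malformed beta matrix file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (ncol(df) < 2) stop("beta matrix needs an ID column plus sample columns", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate probe IDs in beta matrix", call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop("non-numeric cells in beta matrix", call. = FALSE)
  }
  m <- as.matrix(vals)
  if (any(is.na(m))) stop("missing values in beta matrix", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("beta values outside [0, 1]", call. = FALSE)
  rownames(m) <- ids
  m
}
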