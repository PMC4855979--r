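#' Select differentially methylated sites (DMSs)
#'
#' Uniform sample of `S` probe indices without replacement; these probes
#' carry true phenotype associations in the simulation.
#'
#' @param n_probes total number of probes.
#' @param S number of DMSs, `0 <= S <= n_probes`.
#' @param seed integer seed.
#' @return sorted integer vector of DMS indices (possibly empty).
#' @export
select_dms <- function(n_probes, S, seed) {
  if (S > n_probes) stop("S must not exceed n_probes", call. = FALSE)
  if (S < 0) stop("S must be non-negative", call. = FALSE)
  if (S == 0) return(integer(0))
  set.seed(seed)
  sort(sample.int(n_probes, S))
}

#' Generate a phenotype vector
#'
#' @param n number of individuals, >= 2.
#' @param kind `"binary"` for iid Bernoulli(0.5) in `{0, 1}`, or
#'   `"continuous"` for iid standard normal.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
generate_phenotype <- function(n, kind, seed) {
  stopifnot(n >= 2)
  if (!kind %in% c("binary", "continuous")) {
    stop("unknown phenotype kind: ", kind, call. = FALSE)
  }
  set.seed(seed)
  if (kind == "binary") stats::rbinom(n, 1L, 0.5) else stats::rnorm(n)
}

#' Sample probe-level DMS effect means
#'
#' For each DMS probe `j` and cell type `k`, draws the effect mean
#' `mu_jk ~ N(mu_k, sigma_k^2)`. When the scenario defines blocks, effect
#' means within a block are jointly multivariate normal with an
#' equicorrelation structure (the block's background correlation) for each
#' cell type, with block-specific `mu_k`/`sigma_k`; blocks are mutually
#' independent, and the two cell types are never correlated with each other.
#'
#' @param scenario a [scenario_config()].
#' @param seed integer seed.
#' @return an `S x 2` matrix of effect means.
#' @export
sample_effect_means <- function(scenario, seed) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(seed)
  S <- scenario$S
  mu <- matrix(NA_real_, nrow = S, ncol = 2)
  if (S == 0) return(mu)
  if (is.null(scenario$blocks)) {
    for (k in 1:2) {
      mu[, k] <- stats::rnorm(S, mean = scenario$mu_k[k], sd = scenario$sigma_k[k])
    }
  } else {
    start <- 1L
    for (b in scenario$blocks) {
      r <- b$background_correlation
      idx <- start:(start + b$size - 1L)
      for (k in 1:2) {
        # Equicorrelated MVN via a shared factor: sqrt(r) z0 + sqrt(1-r) z_j
        z0 <- stats::rnorm(1)
        zj <- stats::rnorm(b$size)
        mu[idx, k] <- b$mu_k[k] + b$sigma_k[k] * (sqrt(r) * z0 + sqrt(1 - r) * zj)
      }
      start <- start + b$size
    }
  }
  mu
}

#' Sample individual-level DMS effects
#'
#' Draws `e_ijk ~ N(mu_jk, sigma_jk^2)` independently over individuals.
#' When `sigma_jk` is a `c(lo, hi)` range, one value per probe and cell type
#' is drawn uniformly from the range and then held fixed across individuals.
#'
#' @param mu_jk `S x 2` matrix of effect means.
#' @param sigma_jk scalar standard deviation or `c(lo, hi)` uniform range.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return list with `e`: list of two `S x n` matrices (one per cell type),
#'   and `sigma`: the realized `S x 2` matrix of probe/cell sds.
#' @export
sample_individual_effects <- function(mu_jk, sigma_jk, n, seed) {
  stopifnot(is.matrix(mu_jk), ncol(mu_jk) == 2)
  if (any(sigma_jk < 0)) stop("sigma_jk must be non-negative", call. = FALSE)
  set.seed(seed)
  S <- nrow(mu_jk)
  sigma <- if (length(sigma_jk) == 2) {
    matrix(stats::runif(S * 2, sigma_jk[1], sigma_jk[2]), nrow = S)
  } else {
    matrix(sigma_jk, nrow = S, ncol = 2)
  }
  e <- lapply(1:2, function(k) {
    matrix(stats::rnorm(S * n, mean = mu_jk[, k], sd = sigma[, k]), nrow = S, ncol = n)
  })
  list(e = e, sigma = sigma)
}

#' Inject phenotype effects into beta values on the logit scale
#'
#' Computes `beta' = inv_logit(logit(beta) + z * e)` elementwise. Rows are
#' probes, columns are individuals; `z` is recycled across probes.
#'
#' @param beta matrix (or scalar) of beta values in the open interval (0,1).
#' @param z phenotype vector, one value per column of `beta`.
#' @param e effect matrix with the dimensions of `beta`.
#' @return transformed beta values, clipped to `[1e-6, 1 - 1e-6]`.
#' @export
apply_dms_effect <- function(beta, z, e) {
  if (any(beta <= 0 | beta >= 1)) stop("beta must lie strictly in (0, 1)", call. = FALSE)
  lg <- logit(beta)
  if (is.matrix(beta)) {
    stopifnot(length(z) == ncol(beta), all(dim(e) == dim(beta)))
    shift <- sweep(e, 2, z, `*`)
  } else {
    shift <- z * e
  }
  clip_beta(inv_logit(lg + shift))
}

#' Draw phenotype-dependent cell-type mixture proportions
#'
#' For individual `i`, the expected proportions are
#' `alpha(z_i) = alpha0 + z_i * delta_alpha`, and the realized proportions
#' are drawn from `Dirichlet(rho * alpha(z_i))`. Extreme continuous
#' phenotypes can push a component of `alpha(z)` non-positive; components
#' are clipped at `1e-6` and renormalized before drawing, so the Dirichlet
#' parameters stay positive.
#'
#' @param z phenotype vector.
#' @param alpha0 baseline proportions (length 2, positive, sums to 1).
#' @param delta_alpha per-unit-phenotype shift (length 2, sums to 0).
#' @param rho Dirichlet precision, > 0.
#' @param seed integer seed.
#' @return `length(z) x 2` matrix of proportions; rows sum to 1 exactly.
#' @export
sample_mixture_proportions <- function(z, alpha0, delta_alpha, rho, seed) {
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  stopifnot(length(alpha0) == 2, length(delta_alpha) == 2)
  set.seed(seed)
  alpha_z <- matrix(alpha0, nrow = length(z), ncol = 2, byrow = TRUE) +
    outer(z, delta_alpha)
  alpha_z <- pmax(alpha_z, 1e-6)
  alpha_z <- alpha_z / rowSums(alpha_z)
  p <- rdirichlet_mat(length(z), rho * alpha_z)
  colnames(p) <- c("celltype1", "celltype2")
  p
}

#' Mix cell-type-specific profiles with per-individual proportions
#'
#' `beta_f[j, i] = p[i, 1] * beta1[j, i] + p[i, 2] * beta2[j, i]` — the
#' methylation value that would be observed had the mixed tissue been
#' assayed directly. Each mixed value lies between the two cell-type
#' values.
#'
#' @param beta_pair list of two `J x n` matrices.
#' @param p `n x 2` matrix of mixture proportions.
#' @return `J x n` matrix of mixed beta values.
#' @export
mix_profiles <- function(beta_pair, p) {
  b1 <- beta_pair[[1]]; b2 <- beta_pair[[2]]
  if (!all(dim(b1) == dim(b2)) || nrow(p) != ncol(b1) || ncol(p) != 2) {
    stop("dimension mismatch between profiles and proportions", call. = FALSE)
  }
  sweep(b1, 2, p[, 1], `*`) + sweep(b2, 2, p[, 2], `*`)
}

#' Run one replication of a simulation scenario
#'
#' Composes the five simulation steps: (1) draw the DMS set; (2) draw the
#' phenotype; (3) pass non-DMS probes through unchanged; (4) sample
#' hierarchical effects and inject them on the logit scale at DMS probes;
#' (5) mix the two cell types with Dirichlet proportions whose expectation
#' shifts with the phenotype. The DMS set, phenotype, effects and
#' proportions are re-drawn independently in every replication.
#'
#' @param base a `cell_profile_pair` from [generate_base_profiles()] or
#'   built from matrices read with [read_beta_matrix()].
#' @param scenario a [scenario_config()].
#' @param replication replication index (changes all stage seeds).
#' @return an object of class `simulation_result`: `mixed_beta`
#'   (`J x n`), `truth` (list: `dms_indices`, `z`, `mu_jk`, `e_ijk`,
#'   `sigma_jk`, `p_ik`, `scenario`, `seeds`), and `base`.
#' @export
run_scenario <- function(base, scenario, replication = 1L) {
  stopifnot(inherits(base, "cell_profile_pair"), inherits(scenario, "scenario_config"))
  J <- length(base$probe_ids)
  n <- length(base$sample_ids)
  if (scenario$S > J) stop("scenario S exceeds number of probes in base data", call. = FALSE)

  seeds <- c(
    dms = stage_seed(scenario$seed, "dms", replication),
    phenotype = stage_seed(scenario$seed, "phenotype", replication),
    effect_means = stage_seed(scenario$seed, "effect_means", replication),
    individual_effects = stage_seed(scenario$seed, "individual_effects", replication),
    proportions = stage_seed(scenario$seed, "proportions", replication)
  )

  dms <- select_dms(J, scenario$S, seeds[["dms"]])
  z <- generate_phenotype(n, scenario$phenotype, seeds[["phenotype"]])
  mu_jk <- sample_effect_means(scenario, seeds[["effect_means"]])
  eff <- sample_individual_effects(mu_jk, scenario$sigma_jk, n,
                                   seeds[["individual_effects"]])

  beta_prime <- base$beta
  if (length(dms) > 0) {
    for (k in 1:2) {
      beta_prime[[k]][dms, ] <- apply_dms_effect(base$beta[[k]][dms, , drop = FALSE],
                                                 z, eff$e[[k]])
    }
  }

  p_ik <- sample_mixture_proportions(z, scenario$alpha0, scenario$delta_alpha,
                                     scenario$rho, seeds[["proportions"]])
  mixed <- mix_profiles(beta_prime, p_ik)
  dimnames(mixed) <- list(base$probe_ids, base$sample_ids)

  structure(list(
    mixed_beta = mixed,
    truth = list(dms_indices = dms, z = z, mu_jk = mu_jk, e_ijk = eff$e,
                 sigma_jk = eff$sigma, p_ik = p_ik, scenario = scenario,
                 seeds = seeds, replication = as.integer(replication)),
    base = base
  ), class = "simulation_result")
}

#' Run all replications of a scenario
#'
#' @param base a `cell_profile_pair`.
#' @param scenario a [scenario_config()]; `n_replications` controls the
#'   number of independent runs.
#' @return list of `simulation_result`, one per replication.
#' @export
run_replications <- function(base, scenario) {
  lapply(seq_len(scenario$n_replications), function(r) run_scenario(base, scenario, r))
}

#' Serialize a simulation result
#'
#' Writes the mixed beta matrix as TSV plus a truth sidecar: a JSON file
#' with DMS indices, phenotype, proportions and stage seeds.
#'
#' @param sim a `simulation_result`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_simulation_result <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "simulation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta_path <- file.path(dir, paste0(prefix, "_mixed_beta.tsv"))
  write_beta_matrix(sim$mixed_beta, beta_path)
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  tr <- sim$truth
  jsonlite::write_json(list(
    dms_indices = tr$dms_indices, z = tr$z,
    p_ik = unname(tr$p_ik), seeds = as.list(tr$seeds),
    scenario = tr$scenario$name, replication = tr$replication
  ), truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(beta = beta_path, truth = truth_path))
}
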