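# Internal numerical helpers shared across modules.

# Betas are kept strictly inside (0,1) so logit transforms stay finite.
BETA_EPS <- 1e-6

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

clip_beta <- function(b, eps = BETA_EPS) pmin(pmax(b, eps), 1 - eps)

#' Derive a per-stage random seed from a master seed
#'
#' Every stochastic stage of the pipeline (base-data generation, DMS draw,
#' phenotype, effect sampling, mixing proportions, per-method randomness)
#' consumes its own seed derived deterministically from the master seed, a
#' stage label and a replication index. This makes each stage reproducible
#' in isolation and keeps results independent of the order in which methods
#' are run.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. `"dms"`, `"phenotype"`).
#' @param rep replication index (1-based).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage, rep = 1L) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  # Fold the stage label into a small integer hash, then mix with the seed
  # and replication index modulo a Mersenne prime so results fit in 32 bits.
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  m <- 2147483647
  as.integer((as.numeric(seed) * 7919 + h * 104729 + as.numeric(rep) * 130003) %% m)
}

# Dirichlet draws via independent gammas; rows sum to one exactly after
# normalization. alpha may be a vector (shared) or an n x K matrix.
rdirichlet_mat <- function(n, alpha) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = n, ncol = length(alpha), byrow = TRUE)
  stopifnot(nrow(alpha) == n, all(alpha > 0))
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = n)
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
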