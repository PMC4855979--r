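#' Adjustment result container
#'
#' @param method method name.
#' @param covariates `n x K` numeric matrix of estimated covariates
#'   (surrogate variables, factors, or cell proportions); may have zero
#'   columns.
#' @param K_hat estimated or fixed latent dimension.
#' @param proportions optional `n x 2` estimated cell proportions
#'   (reference-based only).
#' @param diagnostics named list of method diagnostics.
#' @return object of class `adjustment_result`.
#' @export
adjustment_result <- function(method, covariates, K_hat,
                              proportions = NULL, diagnostics = list()) {
  covariates <- as.matrix(covariates)
  if (ncol(covariates) > 0 && qr(covariates)$rank < ncol(covariates)) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  structure(list(method = method, covariates = covariates,
                 K_hat = K_hat, proportions = proportions,
                 diagnostics = diagnostics),
            class = "adjustment_result")
}

#' Build a reference profile set from cell-separated data
#'
#' Column-wise mean beta per cell type over a (held-out) cell-separated
#' data set, as used by reference-based composition estimation.
#'
#' @param pair a `cell_profile_pair`.
#' @return list with `probe_ids` and `mean_beta_per_celltype`
#'   (`J x 2` matrix).
#' @export
reference_profiles <- function(pair) {
  stopifnot(inherits(pair, "cell_profile_pair"))
  m <- cbind(rowMeans(pair$beta[[1]]), rowMeans(pair$beta[[2]]))
  dimnames(m) <- list(pair$probe_ids, c("celltype1", "celltype2"))
  list(probe_ids = pair$probe_ids, mean_beta_per_celltype = m)
}

# Exact least squares of y on columns of R under p >= 0, sum(p) = 1.
# K is small, so all active sets (components pinned at zero) are
# enumerated and the feasible candidate with smallest SSR is returned.
simplex_ls <- function(R, y) {
  K <- ncol(R)
  best <- NULL; best_ssr <- Inf
  for (drop_mask in 0:(2^K - 2)) {
    keep <- which(bitwAnd(drop_mask, 2^(seq_len(K) - 1)) == 0)
    Rk <- R[, keep, drop = FALSE]
    A <- crossprod(Rk)
    if (rcond(A) < 1e-12) {
      if (length(keep) == K) stop("singular marker design", call. = FALSE)
      next
    }
    b <- crossprod(Rk, y)
    # KKT system for min ||Rk p - y||^2 s.t. 1'p = 1
    ones <- rep(1, length(keep))
    Ainv_b <- solve(A, b)
    Ainv_1 <- solve(A, ones)
    lambda <- (sum(ones * Ainv_b) - 1) / sum(ones * Ainv_1)
    p_sub <- drop(Ainv_b - lambda * Ainv_1)
    if (all(p_sub >= -1e-10)) {
      p <- numeric(K); p[keep] <- pmax(p_sub, 0); p <- p / sum(p)
      ssr <- sum((drop(R %*% p) - y)^2)
      if (ssr < best_ssr) { best_ssr <- ssr; best <- p }
    }
  }
  if (is.null(best)) {
    # all mass on the single best-fitting column
    ssr1 <- apply(R, 2, function(r) sum((r - y)^2))
    best <- as.numeric(seq_len(K) == which.min(ssr1))
  }
  best
}

# Non-negative least squares by active-set enumeration (small K only).
nnls_small <- function(R, y) {
  K <- ncol(R)
  best <- rep(0, K); best_ssr <- sum(y^2)
  for (drop_mask in 0:(2^K - 2)) {
    keep <- which(bitwAnd(drop_mask, 2^(seq_len(K) - 1)) == 0)
    Rk <- R[, keep, drop = FALSE]
    A <- crossprod(Rk)
    if (rcond(A) < 1e-12) next
    p_sub <- drop(solve(A, crossprod(Rk, y)))
    if (all(p_sub >= -1e-10)) {
      p <- numeric(K); p[keep] <- pmax(p_sub, 0)
      ssr <- sum((drop(R %*% p) - y)^2)
      if (ssr < best_ssr) { best_ssr <- ssr; best <- p }
    }
  }
  best
}

#' Reference-based cell-composition estimation
#'
#' Estimates per-sample cell-type proportions by constrained least squares
#' of the mixed beta values on reference cell-type profiles, using the
#' `marker_count` probes with the largest absolute between-cell-type
#' reference difference, under `p_k >= 0` and `sum(p_k) = 1`.
#'
#' @param mixed_beta `J x n` mixed beta matrix, rows aligned with the
#'   reference probes (matched by rowname when present).
#' @param reference a [reference_profiles()] set.
#' @param marker_count number of marker probes (default 100).
#' @param sum_to_one if `FALSE`, relax the equality to `sum(p_k) <= 1`
#'   (useful when the reference panel may be incomplete); the default
#'   `TRUE` reflects a two-cell-type mixture.
#' @return an `adjustment_result` with `proportions` (`n x 2`) and the
#'   first proportion column as the covariate.
#' @export
estimate_proportions_refbased <- function(mixed_beta, reference,
                                          marker_count = 100L,
                                          sum_to_one = TRUE) {
  ref <- reference$mean_beta_per_celltype
  if (!is.null(rownames(mixed_beta)) && !is.null(rownames(ref))) {
    common <- intersect(rownames(mixed_beta), rownames(ref))
    if (length(common) < marker_count) {
      stop("fewer aligned probes than marker_count", call. = FALSE)
    }
    mixed_beta <- mixed_beta[common, , drop = FALSE]
    ref <- ref[common, , drop = FALSE]
  }
  if (nrow(mixed_beta) != nrow(ref)) stop("probe sets not aligned", call. = FALSE)
  d <- abs(ref[, 1] - ref[, 2])
  markers <- order(d, decreasing = TRUE)[seq_len(min(marker_count, length(d)))]
  Rm <- ref[markers, , drop = FALSE]
  if (qr(Rm)$rank < ncol(Rm)) stop("singular marker design", call. = FALSE)
  Y <- mixed_beta[markers, , drop = FALSE]
  P <- t(apply(Y, 2, function(y) {
    if (sum_to_one) {
      simplex_ls(Rm, y)
    } else {
      # non-negative LS; if its solution leaves the p <= 1 region, the
      # optimum lies on the sum-to-one face
      p <- nnls_small(Rm, y)
      if (sum(p) > 1) p <- simplex_ls(Rm, y)
      p
    }
  }))
  colnames(P) <- colnames(Rm)
  adjustment_result("refbased", covariates = P[, 1, drop = FALSE],
                    K_hat = NA_integer_, proportions = P,
                    diagnostics = list(marker_count = length(markers)))
}

#' Latent-dimension estimation by random matrix theory
#'
#' Standardizes each probe (row), forms the sample correlation matrix
#' across samples, and counts eigenvalues exceeding the Marchenko--Pastur
#' upper bulk edge `(1 + sqrt(n/J))^2` for the matrix's aspect ratio. Under
#' pure noise no eigenvalue exceeds the edge (asymptotically), so the count
#' estimates the number of latent components.
#'
#' @param values `J x n` matrix, probes by samples.
#' @return integer estimated dimension.
#' @export
estimate_latent_dim_rmt <- function(values) {
  n <- ncol(values); J <- nrow(values)
  if (n < 3) stop("need at least 3 samples for dimension estimation", call. = FALSE)
  mu <- rowMeans(values)
  sd <- sqrt(rowSums((values - mu)^2) / (n - 1))
  keep <- sd > 0
  X <- (values[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  Jk <- nrow(X)
  C <- crossprod(X) / Jk
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  edge <- (1 + sqrt(n / Jk))^2
  sum(ev > edge)
}

#' Reference-free latent components
#'
#' Fits the unadjusted probe-wise linear model, concatenates the estimated
#' coefficient matrix and the residual matrix column-wise, and takes the
#' singular value decomposition of the concatenation. The leading `K`
#' probe-space singular vectors define latent methylation directions; each
#' sample's covariate values are its residual projections onto those
#' directions. `K` defaults to the random-matrix estimate on the residual
#' matrix. Standard errors for the adjusted model are obtained downstream
#' by bootstrap ([reffree_bootstrap()]).
#'
#' @param mixed_values `J x n` matrix of methylation values.
#' @param design `n x d` design matrix including intercept and phenotype.
#' @param K optional fixed dimension; estimated when `NULL`.
#' @return an `adjustment_result`; `diagnostics$loadings` holds the
#'   probe-space singular vectors.
#' @export
reffree_components <- function(mixed_values, design, K = NULL) {
  n <- ncol(mixed_values); d <- ncol(design)
  fit <- stats::lm.fit(design, t(mixed_values))
  B <- t(as.matrix(fit$coefficients))      # J x d
  R <- t(as.matrix(fit$residuals))         # J x n
  if (is.null(K)) K <- estimate_latent_dim_rmt(R)
  if (K >= n - qr(design)$rank) {
    stop("latent dimension too large for residual degrees of freedom", call. = FALSE)
  }
  if (K == 0) {
    return(adjustment_result("reffree", matrix(0, n, 0), K_hat = 0L,
                             diagnostics = list(loadings = matrix(0, nrow(mixed_values), 0))))
  }
  sv <- svd(cbind(B, R), nu = K, nv = 0)
  U <- sv$u                                 # J x K probe-space directions
  # Score samples on the centered data rather than the design residuals so
  # that latent variation correlated with the phenotype is retained.
  Y0 <- mixed_values - rowMeans(mixed_values)
  covariates <- crossprod(Y0, U)            # n x K sample projections
  colnames(covariates) <- paste0("RF", seq_len(K))
  adjustment_result("reffree", covariates, K_hat = as.integer(K),
                    diagnostics = list(loadings = U, d = sv$d[seq_len(K)]))
}

#' Bootstrap standard errors for the reference-free adjusted model
#'
#' Resamples individuals with replacement, refits the probe-wise model
#' (phenotype plus reference-free covariates, both re-estimated within each
#' resample), and returns empirical standard errors and normal-approximation
#' p values for the phenotype coefficient.
#'
#' @param mixed_values `J x n` methylation matrix.
#' @param phenotype length-`n` phenotype vector.
#' @param K latent dimension to use in each resample.
#' @param n_boot number of bootstrap samples (default 100).
#' @param seed integer seed.
#' @return data.frame with `coef`, `se`, `t`, `p` per probe.
#' @export
reffree_bootstrap <- function(mixed_values, phenotype, K, n_boot = 100L, seed = 1L) {
  set.seed(seed)
  n <- ncol(mixed_values)
  design <- cbind(intercept = 1, phenotype = phenotype)
  full <- reffree_components(mixed_values, design, K = K)
  Xfull <- cbind(design, full$covariates)
  coef_full <- t(stats::lm.fit(Xfull, t(mixed_values))$coefficients)[, "phenotype"]
  boot <- matrix(NA_real_, nrow(mixed_values), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::var(phenotype[idx]) == 0) next
    db <- cbind(intercept = 1, phenotype = phenotype[idx])
    cb <- tryCatch(reffree_components(mixed_values[, idx], db, K = K),
                   error = function(e) NULL)
    if (is.null(cb)) next
    Xb <- cbind(db, cb$covariates)
    boot[, b] <- t(stats::lm.fit(Xb, t(mixed_values[, idx]))$coefficients)[, "phenotype"]
  }
  se <- apply(boot, 1, stats::sd, na.rm = TRUE)
  tstat <- coef_full / se
  data.frame(coef = coef_full, se = se, t = tstat,
             p = 2 * stats::pnorm(-abs(tstat)))
}

#' Surrogate variable analysis
#'
#' Two-step surrogate variable estimation: (1) the number of surrogate
#' variables is chosen by a permutation test on the eigenvalues of the
#' residual matrix of the full design — each permutation scrambles every
#' probe's residuals independently, and an eigenvalue is retained while its
#' observed variance share exceeds the permutation distribution at the
#' given significance level; (2) surrogate variables are refined by
#' iteratively re-weighted SVD, weighting probes by evidence of association
#' with the current surrogate variables and lack of association with the
#' phenotype, so the surrogates track unmeasured structure rather than the
#' primary effect.
#'
#' @param mixed_values `J x n` methylation matrix (M-values recommended).
#' @param design `n x d` design with intercept and phenotype (phenotype
#'   must be the column named `"phenotype"` or the last column).
#' @param K optional fixed number of surrogate variables.
#' @param n_perm permutations for the eigenvalue test (default 100).
#' @param alpha significance level for eigenvalue retention (default 0.05).
#' @param n_iter reweighting iterations (default 5).
#' @param seed integer seed.
#' @return an `adjustment_result` with `n x K_hat` surrogate variables.
#' @export
sva_surrogates <- function(mixed_values, design, K = NULL, n_perm = 100L,
                           alpha = 0.05, n_iter = 5L, seed = 1L) {
  set.seed(seed)
  n <- ncol(mixed_values)
  if (qr(design)$rank < ncol(design)) stop("degenerate design", call. = FALSE)
  fit <- stats::lm.fit(design, t(mixed_values))
  R <- t(as.matrix(fit$residuals))          # J x n
  if (is.null(K)) {
    K <- permutation_dim(mixed_values, design, n_perm = n_perm, alpha = alpha)
  }
  K <- as.integer(K)
  if (K == 0) {
    return(adjustment_result("sva", matrix(0, n, 0), K_hat = 0L))
  }
  pheno_idx <- if (!is.null(colnames(design)) && "phenotype" %in% colnames(design)) {
    which(colnames(design) == "phenotype")[1]
  } else ncol(design)
  z <- design[, pheno_idx]
  null_design <- design[, -pheno_idx, drop = FALSE]
  R0 <- t(as.matrix(stats::lm.fit(null_design, t(mixed_values))$residuals))

  sv <- svd(R, nu = 0, nv = K)
  G <- sv$v                                  # n x K initial surrogates
  for (it in seq_len(n_iter)) {
    pg <- f_pvalues(mixed_values, cbind(null_design, G),
                    ncol(null_design) + seq_len(K))
    px <- f_pvalues(mixed_values, cbind(null_design, phenotype = z, G),
                    ncol(null_design) + 1L)
    # posterior weight: associated with the surrogates, not with the phenotype
    w <- (1 - local_fdr(pg)) * local_fdr(px)
    sw <- svd(R0 * w, nu = 0, nv = K)
    G <- sw$v
  }
  colnames(G) <- paste0("SV", seq_len(K))
  adjustment_result("sva", G, K_hat = K,
                    diagnostics = list(n_perm = n_perm, alpha = alpha))
}

# Number of residual-matrix eigenvalues whose variance share beats the
# permutation null (Buja-Eyuboglu style); stops at the first failure.
# Each permutation scrambles every probe's values independently and then
# re-residualizes against the design, so observed and permuted spectra are
# compared on matrices of the same residual rank.
permutation_dim <- function(values, design, n_perm = 100L, alpha = 0.05) {
  n <- ncol(values)
  resid_shares <- function(Y) {
    R <- t(as.matrix(stats::lm.fit(design, t(Y))$residuals))
    ev <- eigen(crossprod(R), symmetric = TRUE, only.values = TRUE)$values
    ev / sum(ev)
  }
  obs_share <- resid_shares(values)
  exceed <- integer(n)
  for (b in seq_len(n_perm)) {
    Yp <- t(apply(values, 1, sample))
    exceed <- exceed + (resid_shares(Yp) >= obs_share)
  }
  pvals <- (exceed + 1) / (n_perm + 1)
  K <- 0L
  for (k in seq_len(n)) {
    if (pvals[k] < alpha) K <- K + 1L else break
  }
  K
}

# Local false discovery rate estimate: Storey-style pi0 at lambda = 0.8
# combined with a kernel density of the p values on the logit scale;
# lfdr(p) = pi0 * f0(p) / f(p), truncated to [0, 1] and made monotone in p.
local_fdr <- function(p, eps = 1e-8) {
  p <- pmin(pmax(p, eps), 1 - eps)
  pi0 <- min(max(mean(p >= 0.8) / 0.2, 1e-3), 1)
  x <- log(p / (1 - p))
  dens <- stats::density(x, adjust = 1.5)
  fx <- stats::approx(dens$x, dens$y, xout = x, rule = 2)$y
  # uniform(0,1) density transformed to the logit scale
  f0 <- p * (1 - p)
  lfdr <- pmin(pi0 * f0 / pmax(fx, 1e-12), 1)
  o <- order(p)
  lfdr[o] <- cummax(lfdr[o])
  lfdr
}

# Per-probe F-test p-values for the listed columns of the design.
f_pvalues <- function(values, design, test_cols) {
  n <- ncol(values)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    # collinear extended design: treat tested columns as uninformative
    return(rep(1, nrow(values)))
  }
  full <- stats::lm.fit(design, t(values))
  rss1 <- colSums(as.matrix(full$residuals)^2)
  red <- stats::lm.fit(design[, -test_cols, drop = FALSE], t(values))
  rss0 <- colSums(as.matrix(red$residuals)^2)
  df1 <- length(test_cols)
  df2 <- n - ncol(design)
  f <- pmax(0, (rss0 - rss1) / df1) / (rss1 / df2)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Select negative-control probes
#'
#' Picks `m` probes that are strongly differential between the two cell
#' types (and therefore informative about mixture proportions), excluding
#' true or putative DMSs and probes correlated with the phenotype — the
#' eligibility conditions for a negative control.
#'
#' @param base a `cell_profile_pair` (its `differential_probe_mask` and
#'   logit-mean difference rank candidates) or a logical mask over probes.
#' @param exclude probe indices to exclude (e.g. known DMSs).
#' @param phenotype optional phenotype vector; combined with
#'   `mixed_values`, probes significantly correlated with the phenotype
#'   (correlation-test p below `sig_level`, or absolute correlation above
#'   `cor_threshold` when that is supplied) are dropped.
#' @param mixed_values optional `J x n` matrix for the phenotype screen.
#' @param m number of control probes (default 500).
#' @param sig_level significance level of the phenotype-correlation screen
#'   (default 0.01).
#' @param cor_threshold optional fixed absolute-correlation cutoff that
#'   overrides the significance screen.
#' @return integer vector of `m` control probe indices.
#' @export
select_control_probes <- function(base, exclude = integer(0), phenotype = NULL,
                                  mixed_values = NULL, m = 500L,
                                  sig_level = 0.01, cor_threshold = NULL) {
  if (inherits(base, "cell_profile_pair")) {
    mask <- base$differential_probe_mask
    score <- abs(base$logit_means[, 2] - base$logit_means[, 1])
  } else {
    mask <- as.logical(base)
    score <- as.numeric(mask)
  }
  eligible <- which(mask)
  eligible <- setdiff(eligible, exclude)
  if (!is.null(phenotype) && !is.null(mixed_values) && length(eligible) > 0) {
    r <- abs(stats::cor(t(mixed_values[eligible, , drop = FALSE]), phenotype))
    if (is.null(cor_threshold)) {
      # two-sided correlation-test bound at sig_level
      n <- length(phenotype)
      tcrit <- stats::qt(1 - sig_level / 2, df = n - 2)
      cor_threshold <- tcrit / sqrt(n - 2 + tcrit^2)
    }
    eligible <- eligible[r <= cor_threshold]
  }
  if (length(eligible) < m) {
    stop(sprintf("only %d eligible control probes, %d requested",
                 length(eligible), m), call. = FALSE)
  }
  eligible[order(score[eligible], decreasing = TRUE)][seq_len(m)]
}

#' RUV-4 style negative-control factors
#'
#' Factor analysis (SVD) on the negative-control probe submatrix after the
#' design has been regressed out; the leading `K` sample-space singular
#' vectors are returned as covariates capturing unwanted variation. `K`
#' defaults to 3, the fixed dimension used throughout the study; the
#' random-matrix estimate is reported in the diagnostics for reference.
#'
#' @param mixed_values `J x n` methylation matrix (M-values recommended).
#' @param design `n x d` design matrix.
#' @param controls integer indices of negative-control probes.
#' @param K number of factors (default 3); `K = 0` yields an empty
#'   covariate matrix (downstream test equals unadjusted).
#' @return an `adjustment_result`.
#' @export
ruv4_factors <- function(mixed_values, design, controls, K = 3L) {
  if (K > length(controls)) stop("K exceeds the number of control probes", call. = FALSE)
  n <- ncol(mixed_values)
  if (K == 0) {
    return(adjustment_result("ruv", matrix(0, n, 0), K_hat = 0L))
  }
  Yc <- mixed_values[controls, , drop = FALSE]
  # Factor loadings are estimated on the design-orthogonal part of the
  # controls (so the primary effect cannot leak into them), then the
  # factors are scored on the centered, unprojected controls so that
  # unwanted variation correlated with the phenotype is retained in W.
  Rc <- t(as.matrix(stats::lm.fit(design, t(Yc))$residuals))   # m x n
  K_rmt <- tryCatch(estimate_latent_dim_rmt(Rc), error = function(e) NA_integer_)
  a <- svd(Rc, nu = K, nv = 0)$u                               # m x K loadings
  Y0c <- Yc - rowMeans(Yc)
  W <- crossprod(Y0c, a)                                       # n x K scores
  colnames(W) <- paste0("RUV", seq_len(K))
  adjustment_result("ruv", W, K_hat = as.integer(K),
                    diagnostics = list(K_rmt = K_rmt, n_controls = length(controls)))
}
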