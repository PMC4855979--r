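#' Probe-wise linear model
#'
#' Ordinary least squares of each probe's values on a shared design of
#' intercept, phenotype and optional adjustment covariates; extracts the
#' phenotype coefficient, its standard error, the residual variance and
#' degrees of freedom.
#'
#' @param values `J x n` matrix of methylation values (beta scale by
#'   default in this package; M-values may be supplied instead).
#' @param phenotype length-`n` phenotype vector.
#' @param covariates optional `n x K` matrix of adjustment covariates.
#' @return data.frame with `probe_id`, `coef`, `se`, `t`, `df`, `sigma2`,
#'   `p` (two-sided, from the t distribution).
#' @export
probewise_lm <- function(values, phenotype, covariates = NULL) {
  n <- ncol(values)
  stopifnot(length(phenotype) == n)
  X <- cbind(intercept = 1, phenotype = phenotype)
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (n <= ncol(X)) stop("need more samples than design columns", call. = FALSE)
  fit <- stats::lm.fit(X, t(values))
  coefs <- t(as.matrix(fit$coefficients))
  res <- as.matrix(fit$residuals)
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  v <- solve(crossprod(X))[2, 2]  # (X'X)^-1 entry for the phenotype column
  se <- sqrt(sigma2 * v)
  cf <- coefs[, "phenotype"]
  tstat <- cf / se
  # probes with (numerically) zero residual variance: a zero coefficient is
  # an exact non-effect (p = 1), a non-zero one an exact effect (p -> 0)
  degen <- sigma2 < 1e-24
  if (any(degen)) {
    tstat[degen] <- ifelse(abs(cf[degen]) < 1e-12, 0, sign(cf[degen]) * Inf)
  }
  data.frame(
    probe_id = rownames(values) %||% sprintf("p%d", seq_len(nrow(values))),
    coef = cf, se = se, t = tstat, df = df, sigma2 = sigma2,
    p = 2 * stats::pt(-abs(tstat), df),
    row.names = NULL
  )
}

# Newton inversion of the trigamma function (for moment estimation of the
# prior degrees of freedom); monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks probe-wise residual variances toward a common prior by the
#' standard hierarchical model for microarray-style data: residual
#' variances are scaled chi-square given a true variance with a scaled
#' inverse chi-square prior `(d0, s0^2)`. The prior is estimated by the
#' method of moments on `log sigma^2` unless supplied. The posterior
#' variance `s~^2 = (d0 s0^2 + df s^2) / (d0 + df)` replaces `s^2` in the
#' t statistic, which then has `d0 + df` degrees of freedom.
#'
#' @param fit a [probewise_lm()] result.
#' @param params optional list with `d0` and `s0_sq` to use instead of
#'   estimating them.
#' @return the fit with `se`, `t`, `df`, `p` replaced by their moderated
#'   versions; the estimated `(d0, s0_sq)` are attached as attributes.
#' @export
ebayes_moderate <- function(fit, params = NULL) {
  s2 <- fit$sigma2
  df <- fit$df[1]
  if (is.null(params)) {
    ok <- s2 > 0
    if (sum(ok) < 2 || stats::var(log(s2[ok])) < 1e-15) {
      warning("residual variances are degenerate; returning unmoderated statistics")
      return(fit)
    }
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - trigamma(df / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
    params <- list(d0 = d0, s0_sq = s0_sq)
  }
  if (params$d0 < 0 || params$s0_sq <= 0) stop("invalid moderation parameters", call. = FALSE)
  s2_post <- if (is.infinite(params$d0)) {
    rep(params$s0_sq, length(s2))
  } else {
    (params$d0 * params$s0_sq + df * s2) / (params$d0 + df)
  }
  scale <- sqrt(s2_post / s2)
  out <- fit
  out$se <- fit$se * scale
  out$t <- fit$coef / out$se
  out$df <- min(params$d0 + df, 1e6)
  out$p <- 2 * stats::pt(-abs(out$t), out$df)
  attr(out, "moderation") <- params
  out
}

#' Significance calls at a fixed raw threshold
#'
#' @param p vector of p values in `[0, 1]`.
#' @param threshold significance cutoff; probes with `p` strictly below it
#'   are declared significant (default `1e-4`).
#' @return logical mask.
#' @export
declare_significant <- function(p, threshold = 1e-4) {
  stopifnot(all(p >= 0 & p <= 1))
  p < threshold
}

#' Probe-wise association test with moderation
#'
#' Convenience wrapper: [probewise_lm()] followed by [ebayes_moderate()].
#'
#' @inheritParams probewise_lm
#' @param moderate apply empirical-Bayes moderation (default `TRUE`).
#' @return a moderated association data.frame.
#' @export
assoc_test <- function(values, phenotype, covariates = NULL, moderate = TRUE) {
  fit <- probewise_lm(values, phenotype, covariates)
  if (moderate) ebayes_moderate(fit) else fit
}
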