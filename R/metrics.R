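#' Count false positives against simulation truth
#'
#' Number of non-DMS probes whose p value falls strictly below the
#' threshold.
#'
#' @param p vector of p values over the probe universe.
#' @param dms_truth integer indices of the true DMS probes.
#' @param threshold significance cutoff (default `1e-4`).
#' @return integer count.
#' @export
count_false_positives <- function(p, dms_truth, threshold = 1e-4) {
  stopifnot(all(dms_truth >= 1 & dms_truth <= length(p)))
  idx <- setdiff(seq_along(p), dms_truth)
  sum(p[idx] < threshold)
}

#' Power (sensitivity) against simulation truth
#'
#' Fraction of true DMS probes whose p value falls strictly below the
#' threshold.
#'
#' @inheritParams count_false_positives
#' @return fraction in `[0, 1]`; `NA` with a warning when the DMS set is
#'   empty.
#' @export
compute_power <- function(p, dms_truth, threshold = 1e-4) {
  if (length(dms_truth) == 0) {
    warning("empty DMS set; power is undefined")
    return(NA_real_)
  }
  stopifnot(all(dms_truth >= 1 & dms_truth <= length(p)))
  mean(p[dms_truth] < threshold)
}

#' Kolmogorov-Smirnov distance from Uniform(0,1)
#'
#' The supremum distance between the empirical CDF of the p values and the
#' uniform CDF — a calibration measure, not a test (no p value is
#' computed, since probe-wise tests are dependent).
#'
#' @param p_vec p values in `[0, 1]`; must be non-empty.
#' @return the KS statistic `D` in `[0, 1]`.
#' @export
ks_uniform <- function(p_vec) {
  m <- length(p_vec)
  if (m == 0) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p_vec >= 0 & p_vec <= 1))
  ps <- sort(p_vec)
  i <- seq_len(m)
  max(max(i / m - ps), max(ps - (i - 1) / m))
}

#' Genomic inflation factor as a QQ slope
#'
#' Sorts the retained `-log10` p values against uniform expected quantiles
#' `-log10((i - 0.5)/m)` and returns the least-squares slope through the
#' origin. Equals 1 for well-calibrated p values; values above 1 indicate
#' genome-wide inflation (e.g. from cell-type confounding). The
#' conventional median-chi-square lambda is available via
#' `method = "median_chisq"` as a cross-check.
#'
#' @param p_vec p values.
#' @param exclude indices to drop before computing the slope (typically
#'   the true DMS set); at least 100 p values must remain.
#' @param method `"qq_slope"` (default) or `"median_chisq"`.
#' @return the inflation factor (positive scalar).
#' @export
genomic_inflation <- function(p_vec, exclude = integer(0),
                              method = c("qq_slope", "median_chisq")) {
  method <- match.arg(method)
  p <- if (length(exclude)) p_vec[-exclude] else p_vec
  m <- length(p)
  if (m < 100) stop("need at least 100 p values after exclusion", call. = FALSE)
  if (any(p <= 0)) {
    warning("zero p values clipped at 1e-300")
    p <- pmax(p, 1e-300)
  }
  if (method == "median_chisq") {
    return(stats::qchisq(stats::median(p), df = 1, lower.tail = FALSE) /
             stats::qchisq(0.5, df = 1, lower.tail = FALSE))
  }
  obs <- sort(-log10(p), decreasing = TRUE)
  expd <- -log10((seq_len(m) - 0.5) / m)
  sum(expd * obs) / sum(expd^2)
}

#' QQ table export
#'
#' Sorted observed and expected `-log10` p values (ascending), ready for
#' plotting, with the excluded DMS set recorded.
#'
#' @param p p values over the probe universe.
#' @param dms_truth DMS indices excluded from the QQ points.
#' @return list with a data.frame `table` (columns `expected_neglog10`,
#'   `observed_neglog10`) and `excluded`.
#' @export
export_qq <- function(p, dms_truth = integer(0)) {
  keep <- if (length(dms_truth)) p[-dms_truth] else p
  m <- length(keep)
  obs <- sort(-log10(pmax(keep, 1e-300)))
  expd <- sort(-log10((seq_len(m) - 0.5) / m))
  list(table = data.frame(expected_neglog10 = expd, observed_neglog10 = obs),
       excluded = dms_truth)
}

#' Scorecard of performance metrics per method
#'
#' One row per adjustment method with the number of false positives, power,
#' KS distance and genomic inflation factor, all computed with the true DMS
#' set excluded from KS and GIF (configurable), plus the method's estimated
#' latent dimension.
#'
#' @param assoc_by_method named list of association result data.frames
#'   (from [assoc_test()] or [probewise_lm()]), one per method; each may
#'   carry a `K_hat` attribute.
#' @param truth a `simulation_result` truth list (needs `dms_indices`).
#' @param threshold significance cutoff (default `1e-4`).
#' @param exclude_dms_from_ks compute KS on non-DMS probes only, matching
#'   the GIF exclusion (default `TRUE`).
#' @return data.frame with columns `method`, `nfp`, `power`, `ks`, `gif`,
#'   `K_hat`.
#' @export
build_metrics_table <- function(assoc_by_method, truth, threshold = 1e-4,
                                exclude_dms_from_ks = TRUE) {
  dms <- truth$dms_indices
  nprobe <- NULL
  rows <- lapply(names(assoc_by_method), function(mname) {
    res <- assoc_by_method[[mname]]
    p <- res$p
    if (is.null(nprobe)) nprobe <<- length(p)
    if (length(p) != nprobe) stop("mismatched probe sets across methods", call. = FALSE)
    ks_p <- if (exclude_dms_from_ks && length(dms)) p[-dms] else p
    data.frame(
      method = mname,
      nfp = count_false_positives(p, dms, threshold),
      power = if (length(dms)) compute_power(p, dms, threshold) else NA_real_,
      ks = ks_uniform(ks_p),
      gif = genomic_inflation(p, exclude = dms),
      K_hat = attr(res, "K_hat") %||% NA_integer_
    )
  })
  do.call(rbind, rows)
}
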