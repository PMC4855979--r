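#' Simulation scenario configuration
#'
#' Collects all parameters of the mixture simulation: the number of
#' differentially methylated sites (DMSs) `S`; cell-type-specific DMS effect
#' means `mu_k` and standard deviations `sigma_k`; the individual-level
#' effect standard deviation `sigma_jk` (a scalar, or a `c(lo, hi)` range
#' from which one value per probe and cell type is drawn uniformly each
#' replication); the Dirichlet precision `rho`; baseline mixture proportions
#' `alpha0`; the per-unit-phenotype proportion shift `delta_alpha`; the
#' phenotype kind; an optional block structure coupling DMS effect means;
#' and the replication count.
#'
#' @param name scenario label.
#' @param S number of DMS probes.
#' @param mu_k length-2 numeric, DMS effect mean per cell type.
#' @param sigma_k length-2 non-negative numeric, DMS effect sd per cell type.
#' @param sigma_jk scalar sd, or length-2 `c(lo, hi)` uniform range realized
#'   once per probe and cell type per replication.
#' @param rho Dirichlet precision, > 0; larger means less person-to-person
#'   variation in cell proportions.
#' @param alpha0 length-2 positive baseline proportions summing to 1.
#' @param delta_alpha length-2 shift in expected proportions per unit
#'   phenotype, summing to 0.
#' @param phenotype `"binary"` (Bernoulli(0.5)) or `"continuous"` (standard
#'   normal).
#' @param blocks optional list of blocks, each a list with `size`,
#'   `background_correlation` in `[0, 1)`, `mu_k`, `sigma_k`; block sizes
#'   must sum to `S`. Effect means are equicorrelated within a block and
#'   independent across blocks.
#' @param n_replications number of independent replications.
#' @param seed master seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            S = 500L,
                            mu_k = c(-0.05, 0.5),
                            sigma_k = c(0.05, 0.75),
                            sigma_jk = c(0.1, 2),
                            rho = 100,
                            alpha0 = c(0.57, 0.43),
                            delta_alpha = c(0.08, -0.08),
                            phenotype = c("binary", "continuous"),
                            blocks = NULL,
                            n_replications = 1L,
                            seed = 1L) {
  phenotype <- match.arg(phenotype)
  errs <- character(0)
  if (!is.numeric(S) || length(S) != 1 || S < 0) errs <- c(errs, "S must be a non-negative count")
  if (length(mu_k) != 2) errs <- c(errs, "mu_k must have length 2")
  if (length(sigma_k) != 2 || any(sigma_k < 0)) errs <- c(errs, "sigma_k must be length 2, non-negative")
  if (!length(sigma_jk) %in% 1:2 || any(sigma_jk < 0)) {
    errs <- c(errs, "sigma_jk must be a non-negative scalar or c(lo, hi) range")
  }
  if (length(sigma_jk) == 2 && sigma_jk[2] < sigma_jk[1]) {
    errs <- c(errs, "sigma_jk range must have lo <= hi")
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) errs <- c(errs, "rho must be > 0")
  if (length(alpha0) != 2 || any(alpha0 <= 0)) {
    errs <- c(errs, "alpha0 components must be positive")
  } else if (abs(sum(alpha0) - 1) > 1e-8) {
    errs <- c(errs, "alpha0 must sum to 1")
  }
  if (length(delta_alpha) != 2 || abs(sum(delta_alpha)) > 1e-8) {
    errs <- c(errs, "delta_alpha must be length 2 and sum to 0")
  }
  if (!is.null(blocks)) {
    for (b in blocks) {
      if (is.null(b$size) || is.null(b$background_correlation) ||
          is.null(b$mu_k) || is.null(b$sigma_k)) {
        errs <- c(errs, "each block needs size, background_correlation, mu_k, sigma_k")
        next
      }
      if (b$background_correlation < 0 || b$background_correlation >= 1) {
        errs <- c(errs, "block background_correlation must lie in [0, 1)")
      }
    }
    sizes <- vapply(blocks, function(b) as.numeric(b$size %||% NA_real_), numeric(1))
    if (!anyNA(sizes) && sum(sizes) != S) errs <- c(errs, "block sizes must sum to S")
  }
  if (!is.numeric(n_replications) || n_replications < 1) {
    errs <- c(errs, "n_replications must be a positive count")
  }
  if (length(errs)) {
    stop("invalid scenario configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(
    name = name,
    S = as.integer(S),
    mu_k = as.numeric(mu_k),
    sigma_k = as.numeric(sigma_k),
    sigma_jk = as.numeric(sigma_jk),
    rho = as.numeric(rho),
    alpha0 = as.numeric(alpha0),
    delta_alpha = as.numeric(delta_alpha),
    phenotype = phenotype,
    blocks = blocks,
    n_replications = as.integer(n_replications),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Preset scenario configurations
#'
#' Returns one of the eight study scenarios. All share baseline proportions
#' `alpha0 = (0.57, 0.43)` (monocytes, T cells): (1) distinct differences in
#' DMS effect distributions between cell types; (2) no confounding (equal
#' effects in both cell types); (3) opposite effects; (4) high Dirichlet
#' precision (`rho = 200`); (5) low precision (`rho = 10`); (6) continuous
#' phenotype with `delta_alpha = (0.03, -0.03)`; (7) only 50 DMSs with
#' strong effects, 10 replications; (8) 10,000 DMSs in two equicorrelated
#' blocks of 5,000 (correlations 0.4 and 0.5), 10 replications.
#'
#' @param which scenario number, 1 through 8.
#' @param seed master seed stored in the configuration.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(which, seed = 1L) {
  which <- as.integer(which)
  stopifnot(length(which) == 1L, which >= 1L, which <= 8L)
  base <- list(S = 500L, sigma_jk = 0.1, rho = 100, alpha0 = c(0.57, 0.43),
               delta_alpha = c(0.08, -0.08), phenotype = "binary",
               blocks = NULL, n_replications = 1L, seed = seed)
  p <- switch(which,
    `1` = list(name = "distinct_differences", mu_k = c(-0.05, 0.5),
               sigma_k = c(0.05, 0.75), sigma_jk = c(0.1, 2)),
    `2` = list(name = "no_confounding", mu_k = c(0.25, 0.25), sigma_k = c(0.5, 0.5)),
    `3` = list(name = "opposite_effects", mu_k = c(-0.75, 0.75), sigma_k = c(0.1, 0.1)),
    `4` = list(name = "high_precision", mu_k = c(0.3, 0.1), sigma_k = c(0.1, 0.1),
               rho = 200),
    `5` = list(name = "low_precision", mu_k = c(0.3, 0.1), sigma_k = c(0.1, 0.1),
               rho = 10),
    `6` = list(name = "continuous_phenotype", mu_k = c(-0.05, 0.25),
               sigma_k = c(0.05, 0.15), delta_alpha = c(0.03, -0.03),
               phenotype = "continuous"),
    `7` = list(name = "few_associated_sites", S = 50L, mu_k = c(1, 0.95),
               sigma_k = c(0.05, 0.05), sigma_jk = c(0.1, 2),
               n_replications = 10L),
    `8` = list(name = "many_associated_sites", S = 10000L,
               mu_k = c(0.15, 0.55), sigma_k = c(0.01, 0.01),
               sigma_jk = c(0.1, 2), n_replications = 10L,
               blocks = list(
                 list(size = 5000L, background_correlation = 0.4,
                      mu_k = c(0.1, 0.4), sigma_k = c(0.01, 0.01)),
                 list(size = 5000L, background_correlation = 0.5,
                      mu_k = c(0.2, 0.7), sigma_k = c(0.01, 0.01))
               ))
  )
  args <- utils::modifyList(base, p)
  do.call(scenario_config, args)
}

#' Validate a scenario configuration file
#'
#' Reads a YAML or JSON scenario description, checks every invariant with a
#' field-level message, and returns the parsed [scenario_config()]. Nothing
#' is silently coerced.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [scenario_config()]; invalid files raise an error
#'   listing each violated constraint.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(scenario_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown configuration fields: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$blocks)) {
    raw$blocks <- lapply(raw$blocks, function(b) {
      b$mu_k <- as.numeric(unlist(b$mu_k)); b$sigma_k <- as.numeric(unlist(b$sigma_k)); b
    })
  }
  do.call(scenario_config, raw)
}

#' Write a scenario configuration to YAML
#'
#' @param config a [scenario_config()].
#' @param path output path.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- unclass(config)
  out$S <- as.integer(out$S)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Locate a shipped scenario preset file
#'
#' The eight preset configurations are also shipped as YAML files under
#' `inst/extdata/scenarios/`; this returns the installed path.
#'
#' @param which scenario number 1..8.
#' @return file path.
#' @export
scenario_preset_path <- function(which) {
  f <- system.file("extdata", "scenarios", sprintf("scenario%d.yaml", as.integer(which)),
                   package = "cellmixsim", mustWork = TRUE)
  f
}
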