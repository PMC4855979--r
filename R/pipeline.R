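#' Run the full simulation-adjustment-evaluation pipeline
#'
#' For each replication of a scenario: simulate mixed methylation data from
#' the base cell-separated profiles, estimate adjustment covariates with
#' each requested method, run the probe-wise moderated association test,
#' and score it against the simulation truth. Reference-based adjustment
#' uses a reference panel built from an independently generated
#' cell-separated data set (a fresh draw from the same base configuration),
#' mimicking an external reference. RUV controls are truth-derived:
#' cell-type-differential probes outside the DMS set, screened for
#' phenotype correlation.
#'
#' Method input scales follow the conventions of the original methods:
#' reference-based and reference-free work on beta values; SVA and RUV on
#' logit(beta) M-values. The association test itself runs on beta values.
#'
#' @param scenario a [scenario_config()], preset number 1..8, or a path to
#'   a YAML/JSON configuration file.
#' @param base optional `cell_profile_pair`; generated from
#'   `base_config` when `NULL`.
#' @param base_config a [base_profile_config()] used when `base` is `NULL`
#'   (and, with a shifted seed, for the reference panel).
#' @param methods character vector among `"unadjusted"`, `"refbased"`,
#'   `"reffree"`, `"sva"`, `"ruv"`, or `"plugin:<name>:<path>"` for an
#'   external covariate matrix (TSV, one row per sample).
#' @param n_controls number of RUV negative-control probes (default 500,
#'   reduced to the eligible count floor automatically never — an error is
#'   raised when too few are eligible).
#' @param ruv_k fixed RUV latent dimension (default 3).
#' @param reffree_bootstrap_n bootstrap samples for reference-free standard
#'   errors (default 100); set to 0 to use analytic (model-based) errors.
#' @param outdir optional directory; when given, metrics and the manifest
#'   are written there as TSV/JSON.
#' @param threshold significance cutoff (default `1e-4`).
#' @return list with `metrics` (data.frame, one row per method per
#'   replication), `manifest` (seeds, versions, timestamps) and
#'   `results` (per-replication list of association results and
#'   adjustment objects).
#' @export
run_pipeline <- function(scenario,
                         base = NULL,
                         base_config = base_profile_config(),
                         methods = c("unadjusted", "refbased", "sva", "ruv"),
                         n_controls = 500L,
                         ruv_k = 3L,
                         reffree_bootstrap_n = 100L,
                         outdir = NULL,
                         threshold = 1e-4) {
  if (is.character(scenario) && file.exists(scenario)) {
    scenario <- validate_config(scenario)
  } else if (is.numeric(scenario)) {
    scenario <- scenario_preset(scenario)
  }
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(base)) base <- generate_base_profiles(base_config)

  # Reference panel for the reference-based method: an independent cohort
  # of sorted cells drawn from the same probe-level population.
  reference <- NULL
  if ("refbased" %in% methods) {
    reference <- reference_profiles(
      resample_cohort(base, seed = stage_seed(scenario$seed, "reference_panel"))
    )
  }

  all_metrics <- list()
  all_results <- list()
  for (rep in seq_len(scenario$n_replications)) {
    sim <- run_scenario(base, scenario, rep)
    z <- sim$truth$z
    beta <- sim$mixed_beta
    mvals <- logit(clip_beta(beta))

    assoc <- list()
    adjustments <- list()
    for (m in methods) {
      res <- tryCatch(
        run_one_method(m, sim, beta, mvals, z, reference, base,
                       n_controls = n_controls, ruv_k = ruv_k,
                       reffree_bootstrap_n = reffree_bootstrap_n, rep = rep,
                       scenario = scenario),
        error = function(e) {
          warning(sprintf("method '%s' failed: %s", m, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) next
      label <- res$adjustment$method
      assoc[[label]] <- res$assoc
      adjustments[[label]] <- res$adjustment
    }
    mt <- build_metrics_table(assoc, sim$truth, threshold = threshold)
    mt$replication <- rep
    mt$scenario <- scenario$name
    all_metrics[[rep]] <- mt
    all_results[[rep]] <- list(assoc = assoc, adjustments = adjustments,
                               truth = sim$truth)
  }
  metrics <- do.call(rbind, all_metrics)

  manifest <- list(
    scenario = scenario$name,
    parameters = unclass(scenario),
    n_probes = length(base$probe_ids),
    n_individuals = length(base$sample_ids),
    methods = methods,
    seeds = lapply(seq_len(scenario$n_replications), function(r)
      as.list(all_results[[r]]$truth$seeds)),
    version = as.character(utils::packageVersion("cellmixsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(metrics, file.path(outdir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, manifest = manifest, results = all_results)
}

run_one_method <- function(m, sim, beta, mvals, z, reference, base,
                           n_controls, ruv_k, reffree_bootstrap_n, rep,
                           scenario) {
  truth <- sim$truth
  if (startsWith(m, "plugin:")) {
    parts <- strsplit(m, ":", fixed = TRUE)[[1]]
    covar <- read_plugin_covariates(parts[3], n = length(z))
    adj <- adjustment_result(parts[2], covar, K_hat = ncol(covar))
  } else {
    adj <- switch(m,
      unadjusted = adjustment_result("unadjusted", matrix(0, length(z), 0),
                                     K_hat = NA_integer_),
      refbased = estimate_proportions_refbased(beta, reference),
      reffree = reffree_components(beta, cbind(intercept = 1, phenotype = z)),
      sva = sva_surrogates(mvals, cbind(intercept = 1, phenotype = z),
                           seed = stage_seed(scenario$seed, "sva", rep)),
      ruv = {
        controls <- select_control_probes(base, exclude = truth$dms_indices,
                                          phenotype = z, mixed_values = mvals,
                                          m = n_controls)
        ruv4_factors(mvals, cbind(intercept = 1, phenotype = z), controls,
                     K = ruv_k)
      },
      stop("unknown method: ", m)
    )
  }
  if (identical(adj$method, "reffree") && reffree_bootstrap_n > 0 &&
      adj$K_hat > 0) {
    assoc <- reffree_bootstrap(beta, z, K = adj$K_hat,
                               n_boot = reffree_bootstrap_n,
                               seed = stage_seed(scenario$seed, "reffree_boot", rep))
  } else {
    assoc <- assoc_test(beta, z, covariates = adj$covariates)
  }
  attr(assoc, "K_hat") <- adj$K_hat
  list(assoc = assoc, adjustment = adj)
}

# Plug-in adapter: an external method communicates through a TSV covariate
# matrix (one row per sample, one column per covariate, no header
# required). Failures are raised and isolated by the caller.
read_plugin_covariates <- function(path, n) {
  if (!file.exists(path)) stop("plugin covariate file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (nrow(m) != n) stop("plugin covariates have wrong number of rows", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Aggregate replicated metrics
#'
#' Summarizes a [run_pipeline()] metrics table across replications (the
#' shape used for box plots in replicated scenarios): per method, the
#' median and interquartile range of each metric.
#'
#' @param metrics a metrics data.frame from [run_pipeline()].
#' @return data.frame with one row per method and metric.
#' @export
summarize_replications <- function(metrics) {
  vars <- c("nfp", "power", "ks", "gif")
  out <- do.call(rbind, lapply(split(metrics, metrics$method), function(d) {
    do.call(rbind, lapply(vars, function(v) data.frame(
      method = d$method[1], metric = v,
      median = stats::median(d[[v]], na.rm = TRUE),
      q1 = unname(stats::quantile(d[[v]], 0.25, na.rm = TRUE)),
      q3 = unname(stats::quantile(d[[v]], 0.75, na.rm = TRUE)),
      n_replications = nrow(d)
    )))
  }))
  rownames(out) <- NULL
  out
}
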