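# Shared fixtures, built in code at test time.

make_base <- function(J = 2000, n = 40, seed = 11, frac = 0.2, latent = 0, ...) {
  generate_base_profiles(base_profile_config(
    n_probes = J, n_individuals = n, frac_celltype_differential = frac,
    n_latent_factors = latent, seed = seed, ...
  ))
}

# Small confounded scenario-1-style simulation used by several tests.
make_confounded_sim <- function(J = 3000, n = 46, S = 100, base_seed = 7,
                                scenario_seed = 1) {
  base <- make_base(J = J, n = n, seed = base_seed)
  sc <- scenario_preset(1, seed = scenario_seed)
  sc$S <- as.integer(S)
  list(base = base, scenario = sc, sim = run_scenario(base, sc))
}

# Data with one planted latent confounder driving a fraction of probes:
# Y[j, i] = mu_j + lambda_j * conf_i + eps, with the confounder mildly
# correlated with the phenotype.
make_planted_confounder <- function(J = 2000, n = 40, frac_driven = 0.2,
                                    loading_sd = 1, noise_sd = 0.5, seed = 3) {
  set.seed(seed)
  z <- rep(0:1, length.out = n)
  conf <- 0.4 * z + rnorm(n, sd = 0.8)
  lambda <- numeric(J)
  driven <- seq_len(round(frac_driven * J))
  lambda[driven] <- rnorm(length(driven), sd = loading_sd)
  Y <- matrix(rnorm(J * n, sd = noise_sd), J, n) + outer(lambda, conf)
  list(Y = Y, z = z, conf = conf, driven = driven, lambda = lambda)
}
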