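test_that("DMS selection covers the degenerate and full cases and is unique", {
  expect_identical(select_dms(100, 0, 1), integer(0))
  expect_identical(select_dms(10, 10, 1), 1:10)
  dms <- select_dms(375639, 500, 42)
  expect_length(dms, 500)
  expect_false(anyDuplicated(dms) > 0)
  expect_true(all(dms >= 1 & dms <= 375639))
  expect_error(select_dms(10, 11, 1), "exceed")
})

test_that("phenotype generation matches its distributional oracle", {
  zb <- generate_phenotype(1e5, "binary", 2)
  expect_true(all(zb %in% c(0, 1)))
  expect_lt(abs(mean(zb) - 0.5), 0.005)  # binomial 99% band: +/- 0.0041
  zc <- generate_phenotype(1e5, "continuous", 2)
  expect_lt(abs(sd(zc) - 1), 0.01)       # chi-square band on the sample sd
  expect_error(generate_phenotype(100, "ordinal", 1), "unknown")
})

test_that("effect means have the configured per-cell-type distributions", {
  sc <- scenario_preset(1)
  mu <- sample_effect_means(sc, seed = 9)
  expect_equal(dim(mu), c(500L, 2L))
  # distinct-differences preset: means near -0.05 and 0.5
  expect_lt(abs(mean(mu[, 1]) - (-0.05)), 4 * 0.05 / sqrt(500))
  expect_lt(abs(mean(mu[, 2]) - 0.5), 4 * 0.75 / sqrt(500))
  # zero-sd degeneracy
  sc0 <- scenario_config(S = 10, mu_k = c(0.3, -0.2), sigma_k = c(0, 0),
                         sigma_jk = 0.1)
  mu0 <- sample_effect_means(sc0, seed = 1)
  expect_true(all(mu0[, 1] == 0.3) && all(mu0[, 2] == -0.2))
})

test_that("blocked effect means realize the configured background correlation", {
  blocks <- list(list(size = 10L, background_correlation = 0.4,
                      mu_k = c(0.1, 0.4), sigma_k = c(1, 1)))
  sc <- scenario_config(S = 10, sigma_jk = 0.1, blocks = blocks)
  draws <- vapply(1:4000, function(s) sample_effect_means(sc, seed = s)[1:2, 1],
                  numeric(2))
  r <- cor(draws[1, ], draws[2, ])
  expect_lt(abs(r - 0.4), 0.05)  # MC se of r at 4000 draws ~ 0.013
  # probes in different blocks are independent
  blocks2 <- list(list(size = 5L, background_correlation = 0.5,
                       mu_k = c(0, 0), sigma_k = c(1, 1)),
                  list(size = 5L, background_correlation = 0.5,
                       mu_k = c(0, 0), sigma_k = c(1, 1)))
  sc2 <- scenario_config(S = 10, sigma_jk = 0.1, blocks = blocks2)
  draws2 <- vapply(1:4000, function(s) sample_effect_means(sc2, seed = s)[c(1, 6), 1],
                   numeric(2))
  expect_lt(abs(cor(draws2[1, ], draws2[2, ])), 0.06)
})

test_that("individual effects honor sigma_jk as a scalar and as a range", {
  mu <- matrix(0, nrow = 200, ncol = 2)
  e0 <- sample_individual_effects(mu, 0, n = 5, seed = 1)
  expect_true(all(e0$e[[1]] == 0) && all(e0$e[[2]] == 0))
  eN <- sample_individual_effects(matrix(0, 1000, 2), 1, n = 100, seed = 2)
  expect_lt(abs(mean(eN$e[[1]])), 0.01)  # CLT band at 1e5 draws
  eR <- sample_individual_effects(mu, c(0.1, 2), n = 3, seed = 3)
  expect_true(all(eR$sigma >= 0.1 & eR$sigma <= 2))
  expect_error(sample_individual_effects(mu, -1, 3, 1), "non-negative")
})

test_that("logit-scale effect injection matches the closed form", {
  expect_equal(apply_dms_effect(0.5, 0, 5), 0.5)
  expect_equal(apply_dms_effect(0.5, 1, log(3)), 0.75)
  expect_equal(apply_dms_effect(0.2, 1, 1.0),
               1 / (1 + exp(-(log(0.2 / 0.8) + 1))), tolerance = 1e-12)
  # monotone: positive effect and phenotype raise methylation
  b <- matrix(runif(50, 0.05, 0.95), 10, 5)
  e <- matrix(abs(rnorm(50)) + 0.01, 10, 5)
  out <- apply_dms_effect(b, rep(1, 5), e)
  expect_true(all(out > b))
  expect_error(apply_dms_effect(1.2, 1, 0), "strictly")
})

test_that("mixture proportions follow the Dirichlet model", {
  p <- sample_mixture_proportions(rep(0, 1000), c(0.57, 0.43), c(0.08, -0.08),
                                  rho = 100, seed = 5)
  expect_equal(rowSums(p), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # variance law: var(p1) = a1 a2 / (rho + 1)
  p_hi <- sample_mixture_proportions(rep(0, 20000), c(0.57, 0.43), c(0, 0), 100, 6)
  p_lo <- sample_mixture_proportions(rep(0, 20000), c(0.57, 0.43), c(0, 0), 10, 6)
  expect_lt(var(p_hi[, 1]), var(p_lo[, 1]))
  expect_equal(var(p_hi[, 1]), 0.57 * 0.43 / 101, tolerance = 0.1)
  expect_equal(var(p_lo[, 1]), 0.57 * 0.43 / 11, tolerance = 0.1)
  expect_error(sample_mixture_proportions(0, c(0.5, 0.5), c(0, 0), -1, 1), "rho")
})

test_that("extreme continuous phenotypes keep Dirichlet parameters positive", {
  z <- c(-50, 50)
  p <- sample_mixture_proportions(z, c(0.57, 0.43), c(0.08, -0.08), 100, 1)
  expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
})

test_that("profile mixing is the stated convex combination", {
  b1 <- matrix(0.2, 3, 2); b2 <- matrix(0.6, 3, 2)
  p <- matrix(c(1, 0.5, 0, 0.5), 2, 2)
  out <- mix_profiles(list(b1, b2), p)
  expect_equal(out[, 1], rep(0.2, 3))
  expect_equal(out[, 2], rep(0.4, 3))
  p2 <- matrix(c(0.57, 0.43), 1, 2)
  expect_equal(as.numeric(mix_profiles(list(matrix(0, 1, 1), matrix(1, 1, 1)), p2)),
               0.43)
  expect_error(mix_profiles(list(b1, b2[, 1, drop = FALSE]), p), "mismatch")
})

test_that("non-DMS probes pass through as convex combinations of base values", {
  fx <- make_confounded_sim(J = 800, n = 20, S = 50)
  sim <- fx$sim
  non_dms <- setdiff(seq_len(800), sim$truth$dms_indices)
  lo <- pmin(fx$base$beta[[1]][non_dms, ], fx$base$beta[[2]][non_dms, ])
  hi <- pmax(fx$base$beta[[1]][non_dms, ], fx$base$beta[[2]][non_dms, ])
  expect_true(all(sim$mixed_beta[non_dms, ] >= lo - 1e-12))
  expect_true(all(sim$mixed_beta[non_dms, ] <= hi + 1e-12))
})

test_that("mixed values always lie between the two cell-type-specific values", {
  fx <- make_confounded_sim(J = 500, n = 15, S = 100)
  sim <- fx$sim
  # recompute beta_prime from truth to bound every entry including DMSs
  bp <- fx$base$beta
  dms <- sim$truth$dms_indices
  for (k in 1:2) {
    bp[[k]][dms, ] <- apply_dms_effect(fx$base$beta[[k]][dms, ],
                                       sim$truth$z, sim$truth$e_ijk[[k]])
  }
  lo <- pmin(bp[[1]], bp[[2]]); hi <- pmax(bp[[1]], bp[[2]])
  expect_true(all(sim$mixed_beta >= lo - 1e-12 & sim$mixed_beta <= hi + 1e-12))
})

test_that("confounding is injected by construction", {
  z <- rep(0:1, each = 4000)
  p <- sample_mixture_proportions(z, c(0.57, 0.43), c(0.08, -0.08), 100, 3)
  diff <- mean(p[z == 1, 1]) - mean(p[z == 0, 1])
  expect_lt(abs(diff - 0.08), 0.004)
})

test_that("simulation results are bit-identical given config and seed", {
  base <- make_base(J = 300, n = 12, seed = 5)
  sc <- scenario_preset(3, seed = 77); sc$S <- 30L
  s1 <- run_scenario(base, sc)
  s2 <- run_scenario(base, sc)
  expect_identical(s1, s2)
  s3 <- run_scenario(base, sc, replication = 2)
  expect_false(identical(s1$mixed_beta, s3$mixed_beta))
  expect_false(identical(s1$truth$dms_indices, s3$truth$dms_indices))
})

test_that("replications redraw the DMS set and sigma_jk ranges", {
  base <- make_base(J = 500, n = 10, seed = 2)
  sc <- scenario_preset(7, seed = 3)  # S = 50, sigma_jk range, 10 replications
  sc$n_replications <- 3L
  reps <- run_replications(base, sc)
  expect_length(reps, 3)
  expect_length(reps[[1]]$truth$dms_indices, 50)
  dms_sets <- lapply(reps, function(s) s$truth$dms_indices)
  expect_false(identical(dms_sets[[1]], dms_sets[[2]]))
  sig <- lapply(reps, function(s) s$truth$sigma_jk)
  expect_false(identical(sig[[1]], sig[[2]]))
  expect_true(all(vapply(sig, function(s) all(s >= 0.1 & s <= 2), logical(1))))
})

test_that("scenario presets encode the study parameterizations", {
  s7 <- scenario_preset(7)
  expect_equal(s7$S, 50L)
  expect_equal(s7$n_replications, 10L)
  s8 <- scenario_preset(8)
  expect_equal(s8$S, 10000L)
  expect_equal(vapply(s8$blocks, function(b) b$size, integer(1)), c(5000L, 5000L))
  expect_equal(vapply(s8$blocks, function(b) b$background_correlation, numeric(1)),
               c(0.4, 0.5))
  s6 <- scenario_preset(6)
  expect_equal(s6$phenotype, "continuous")
  expect_equal(s6$delta_alpha, c(0.03, -0.03))
  for (i in 1:8) expect_s3_class(scenario_preset(i), "scenario_config")
})

test_that("a null scenario yields no phenotype signal downstream", {
  base <- make_base(J = 2000, n = 46, seed = 31)
  sc <- scenario_config(S = 0L, delta_alpha = c(0, 0), sigma_jk = 0.1, seed = 8)
  sim <- run_scenario(base, sc)
  fit <- assoc_test(sim$mixed_beta, sim$truth$z)
  gif <- genomic_inflation(fit$p)
  expect_lt(abs(gif - 1), 0.25)
})

test_that("simulation results serialize with a complete truth sidecar", {
  fx <- make_confounded_sim(J = 200, n = 10, S = 20)
  dir <- withr::local_tempdir()
  paths <- write_simulation_result(fx$sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(sort(truth$dms_indices), fx$sim$truth$dms_indices)
  expect_equal(truth$z, fx$sim$truth$z)
  back <- read_beta_matrix(paths[["beta"]])
  expect_equal(back, fx$sim$mixed_beta, tolerance = 0)
})
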