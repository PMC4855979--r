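test_that("reference-based estimation is exact on noiseless mixtures", {
  base <- make_base(J = 1000, n = 10, seed = 13)
  ref <- reference_profiles(base)
  R <- ref$mean_beta_per_celltype
  # sample equal to the cell-type-1 profile
  y1 <- R[, 1, drop = FALSE]
  est1 <- estimate_proportions_refbased(y1, ref)
  expect_equal(unname(est1$proportions[1, ]), c(1, 0), tolerance = 1e-8)
  # exact mixture at p = (0.3, 0.7)
  y <- 0.3 * R[, 1] + 0.7 * R[, 2]
  est <- estimate_proportions_refbased(matrix(y, dimnames = list(rownames(R), "s1")), ref)
  expect_equal(unname(est$proportions[1, ]), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("reference-based proportions track the truth on confounded data", {
  fx <- make_confounded_sim(J = 3000, n = 46, S = 100)
  ref <- reference_profiles(resample_cohort(fx$base, seed = 101))
  est <- estimate_proportions_refbased(fx$sim$mixed_beta, ref)
  expect_gt(cor(est$proportions[, 1], fx$sim$truth$p_ik[, 1]), 0.9)
  expect_true(all(est$proportions >= 0 & est$proportions <= 1))
  expect_equal(unname(rowSums(est$proportions)), rep(1, 46), tolerance = 1e-8)
})

test_that("the relaxed constraint recovers sub-unity compositions", {
  base <- make_base(J = 500, n = 8, seed = 13)
  ref <- reference_profiles(base)
  R <- ref$mean_beta_per_celltype
  y <- matrix(0.24 * R[, 1] + 0.56 * R[, 2], dimnames = list(rownames(R), "s1"))
  est <- estimate_proportions_refbased(y, ref, sum_to_one = FALSE)
  expect_equal(unname(est$proportions[1, ]), c(0.24, 0.56), tolerance = 1e-6)
  full <- matrix(0.3 * R[, 1] + 0.7 * R[, 2], dimnames = list(rownames(R), "s1"))
  est2 <- estimate_proportions_refbased(full, ref, sum_to_one = FALSE)
  expect_equal(unname(est2$proportions[1, ]), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("a constant reference panel is rejected as singular", {
  ref <- list(probe_ids = paste0("cg", 1:200),
              mean_beta_per_celltype = matrix(0.5, 200, 2))
  y <- matrix(runif(200), 200, 1)
  expect_error(estimate_proportions_refbased(y, ref, marker_count = 50), "singular")
})

test_that("the RMT estimator matches Marchenko-Pastur oracles", {
  # pure-noise matrices: no eigenvalue beyond the bulk edge in >= 95% of seeds
  zeros <- vapply(1:20, function(s) {
    set.seed(s)
    estimate_latent_dim_rmt(matrix(rnorm(2000 * 50), 2000, 50)) == 0L
  }, logical(1))
  expect_gte(mean(zeros), 0.95)
  # planted rank-3 structure with large spectral gaps
  set.seed(7)
  U <- matrix(rnorm(2000 * 3), 2000, 3)
  V <- matrix(rnorm(50 * 3), 50, 3)
  X <- U %*% (diag(c(6, 5, 4))) %*% t(V) + matrix(rnorm(2000 * 50), 2000, 50)
  expect_equal(estimate_latent_dim_rmt(X), 3L)
  # duplicated single row: rank one
  row <- rnorm(30)
  expect_equal(estimate_latent_dim_rmt(matrix(row, 100, 30, byrow = TRUE)), 1L)
  expect_error(estimate_latent_dim_rmt(matrix(rnorm(10), 5, 2)), "at least 3")
})

test_that("reference-free components recover planted structure", {
  # zero-residual rank-1 data: the first singular direction is the loading
  set.seed(5)
  load <- rnorm(400); score <- rnorm(30)
  Y <- outer(load, score)
  rf <- reffree_components(Y, cbind(1, rep(0:1, 15)), K = 1)
  u <- rf$diagnostics$loadings[, 1]
  expect_gt(abs(cor(u, load)), 0.999)
  # planted strong latent factor: leading component tracks the factor
  pl <- make_planted_confounder(J = 2000, n = 40, loading_sd = 2, seed = 8)
  rf2 <- reffree_components(pl$Y, cbind(intercept = 1, phenotype = pl$z), K = 2)
  r <- summary(lm(pl$conf ~ rf2$covariates))$r.squared
  expect_gt(sqrt(r), 0.9)
})

test_that("reference-free dimension stays small on pure noise", {
  set.seed(12)
  Y <- matrix(rnorm(2000 * 30), 2000, 30)
  z <- rep(0:1, 15)
  rf <- reffree_components(Y, cbind(intercept = 1, phenotype = z))
  expect_lte(rf$K_hat, 2)
  if (rf$K_hat > 0) {
    expect_true(all(abs(cor(rf$covariates, z)) < 0.5))
  }
  expect_error(reffree_components(Y, cbind(1, z), K = 29), "degrees of freedom")
})

test_that("SVA recovers a planted confounder and is deterministic", {
  pl <- make_planted_confounder(J = 2000, n = 40, frac_driven = 0.2, seed = 3)
  sv <- sva_surrogates(pl$Y, cbind(intercept = 1, phenotype = pl$z), seed = 4)
  expect_gte(sv$K_hat, 1)
  r <- summary(lm(pl$conf ~ sv$covariates))$r.squared
  expect_gt(sqrt(r), 0.9)
  sv2 <- sva_surrogates(pl$Y, cbind(intercept = 1, phenotype = pl$z), seed = 4)
  expect_identical(sv$covariates, sv2$covariates)
})

test_that("SVA estimates dimension zero on iid noise", {
  zeros <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Y <- matrix(rnorm(1000 * 30), 1000, 30)
    z <- rep(0:1, 15)
    sva_surrogates(Y, cbind(intercept = 1, phenotype = z),
                   n_perm = 100, seed = s)$K_hat == 0L
  }, logical(1))
  expect_gte(mean(zeros), 0.8)
})

test_that("SVA agrees with the independent surrogate-variable oracle", {
  skip_if_not_installed("sva")
  fx <- make_confounded_sim(J = 2000, n = 46, S = 50)
  M <- log(fx$sim$mixed_beta / (1 - fx$sim$mixed_beta))
  z <- fx$sim$truth$z
  mine <- sva_surrogates(M, cbind(intercept = 1, phenotype = z), seed = 1)
  ref <- NULL
  invisible(capture.output(
    ref <- sva::sva(M, cbind(1, z), cbind(rep(1, length(z))))
  ))
  p1 <- fx$sim$truth$p_ik[, 1]
  r_mine <- summary(lm(p1 ~ mine$covariates))$r.squared
  r_orac <- summary(lm(p1 ~ ref$sv))$r.squared
  expect_gt(r_mine, 0.85)
  expect_gt(r_mine, r_orac - 0.1)
})

test_that("control-probe selection respects eligibility rules", {
  base <- make_base(J = 5000, n = 20, seed = 17, frac = 0.3)
  dms <- select_dms(5000, 200, 1)
  ctrl <- select_control_probes(base, exclude = dms, m = 500)
  expect_length(ctrl, 500)
  expect_length(intersect(ctrl, dms), 0)
  expect_true(all(base$differential_probe_mask[ctrl]))
  # all candidates excluded -> error with count
  expect_error(
    select_control_probes(rep(FALSE, 100), m = 10),
    "0 eligible"
  )
  # synthetic mask with exactly 1000 differential probes and no DMS overlap
  mask <- c(rep(TRUE, 1000), rep(FALSE, 4000))
  ctrl2 <- select_control_probes(mask, m = 500)
  expect_true(all(ctrl2 <= 1000))
})

test_that("RUV-4 factors capture a confounder loading on the controls", {
  pl <- make_planted_confounder(J = 2000, n = 40, frac_driven = 0.25,
                                loading_sd = 2, seed = 6)
  controls <- pl$driven[seq_len(400)]
  rv <- ruv4_factors(pl$Y, cbind(intercept = 1, phenotype = pl$z), controls, K = 3)
  r <- summary(lm(pl$conf ~ rv$covariates))$r.squared
  expect_gt(sqrt(r), 0.9)
  expect_equal(rv$K_hat, 3L)
  expect_error(ruv4_factors(pl$Y, cbind(1, pl$z), controls, K = 500), "exceeds")
})

test_that("RUV with K = 0 reduces to the unadjusted analysis", {
  pl <- make_planted_confounder(J = 500, n = 20, seed = 9)
  rv <- ruv4_factors(pl$Y, cbind(intercept = 1, phenotype = pl$z), 1:100, K = 0)
  expect_equal(ncol(rv$covariates), 0L)
  a0 <- assoc_test(pl$Y, pl$z)
  a1 <- assoc_test(pl$Y, pl$z, covariates = rv$covariates)
  expect_equal(a0$p, a1$p)
})

test_that("noise controls leave the inflation near the unadjusted level", {
  fx <- make_confounded_sim(J = 3000, n = 46, S = 60)
  z <- fx$sim$truth$z
  set.seed(44)
  Y <- fx$sim$mixed_beta
  noise_rows <- matrix(runif(300 * 46, 0.4, 0.6), 300, 46,
                       dimnames = list(paste0("nz", 1:300), colnames(Y)))
  Y2 <- rbind(Y, noise_rows)
  rv <- ruv4_factors(Y2, cbind(intercept = 1, phenotype = z),
                     controls = 3000 + seq_len(300), K = 3)
  a0 <- assoc_test(Y, z)
  a1 <- assoc_test(Y, z, covariates = rv$covariates)
  g0 <- genomic_inflation(a0$p, exclude = fx$sim$truth$dms_indices)
  g1 <- genomic_inflation(a1$p, exclude = fx$sim$truth$dms_indices)
  expect_lt(abs(g1 - g0), 0.15)
})

test_that("adjustment covariates keep the design full rank", {
  fx <- make_confounded_sim(J = 1000, n = 30, S = 40)
  z <- fx$sim$truth$z
  M <- log(fx$sim$mixed_beta / (1 - fx$sim$mixed_beta))
  for (adj in list(
    sva_surrogates(M, cbind(intercept = 1, phenotype = z), K = 3, seed = 1),
    reffree_components(fx$sim$mixed_beta, cbind(intercept = 1, phenotype = z), K = 3)
  )) {
    X <- cbind(1, z, adj$covariates)
    expect_equal(qr(X)$rank, ncol(X))
  }
})
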