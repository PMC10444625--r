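# Synthetic cohort generator: genotypes, factors, items, phenotype,
# selection and follow-up.

test_that("configuration is validated", {
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(h2_factor = 1.2), "h2_factor")
  expect_error(sim_config(general_loading = 0.9, domain_loading = 0.6),
               "must be < 1")
  expect_error(sim_config(n_causal = 500, n_variants = 100), "n_causal")
})

test_that("genotypes honour MAF range, LD structure and determinism", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 100, ld_rho = 0,
                    n_causal = 20, seed = 101)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  R2 <- cor(g$dosage)^2
  diag(R2) <- NA
  expect_lt(mean(R2, na.rm = TRUE), 0.01)

  cfg2 <- sim_config(n_individuals = 10000, n_variants = 60,
                     maf_range = c(0.3, 0.3), n_causal = 10, seed = 102)
  g2 <- simulate_genotypes(cfg2)
  freq <- colMeans(g2$dosage) / 2
  # exact binomial bound: 2n * 10000 draws at p = 0.3
  ci <- qbinom(c(2.5e-5, 1 - 2.5e-5), 2 * 10000, 0.3) / (2 * 10000)
  expect_true(all(freq > ci[1] & freq < ci[2]))
  expect_true(all(freq > 0.27 & freq < 0.33))

  cfg3 <- sim_config(n_individuals = 5000, n_variants = 40, ld_rho = 0.6,
                     ld_block_size = 10, n_causal = 10, seed = 103)
  g3 <- simulate_genotypes(cfg3)
  C <- cor(g3$dosage)
  within <- C[1:10, 1:10][upper.tri(diag(10))]
  across <- C[1:10, 11:20]
  expect_gt(mean(within), 0.2)    # copula rho attenuates on the dosage scale
  expect_lt(mean(abs(across)), 0.05)

  expect_identical(simulate_genotypes(cfg)$dosage, g$dosage)
})

test_that("nonresponse factors have the configured heritability and correlation", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 100, ld_rho = 0,
                    h2_factor = 0.2, factor_cor = 0.73, n_causal = 20,
                    seed = 111)
  g <- simulate_genotypes(cfg)
  tr <- simulate_nonresponse_factors(g, cfg)
  expect_equal(cor(tr$general$pna, tr$general$idk), 0.73, tolerance = 0.03)
  h2 <- he_h2(g$dosage, tr$general$pna)
  expect_gt(h2, 0.15)
  expect_lt(h2, 0.25)

  # zero genetic path: factor independent of genotypes
  cfg0 <- sim_config(n_individuals = 10000, n_variants = 100, ld_rho = 0,
                     beta_snp_nonresponse = 0, n_causal = 20, seed = 112)
  tr0 <- simulate_nonresponse_factors(g, cfg0)
  expect_lt(max(abs(cor(g$dosage, tr0$general$pna))), 0.05)
})

test_that("item responses follow the liability model with exclusive codes", {
  cfg <- sim_config(n_individuals = 50000, n_items = 12, n_domains = 3,
                    general_loading = 0.7, domain_loading = 0,
                    item_threshold_range = c(0, 0), n_causal = 20,
                    seed = 121)
  co_tr <- simulate_nonresponse_factors(simulate_genotypes(cfg), cfg)
  it <- simulate_item_responses(co_tr, cfg)
  expect_false(any(it == -3 & it == -1))
  # implied tetrachoric between items: lambda_i * lambda_j = 0.49
  tabfun <- function(i, j) {
    bi <- it[, i] == -3; bj <- it[, j] == -3
    matrix(c(sum(!bi & !bj), sum(!bi & bj), sum(bi & !bj), sum(bi & bj)),
           2, byrow = TRUE)
  }
  r12 <- tetrachoric_rho(tabfun(1, 2))$rho
  expect_equal(r12, 0.49, tolerance = 0.03)

  # zero loadings: items uncorrelated
  cfg0 <- sim_config(n_individuals = 20000, n_items = 6,
                     general_loading = 1e-9, domain_loading = 0,
                     item_threshold_range = c(0.5, 1), n_causal = 20,
                     seed = 122)
  tr0 <- simulate_nonresponse_factors(simulate_genotypes(cfg0), cfg0)
  it0 <- simulate_item_responses(tr0, cfg0)
  R0 <- tetrachoric_matrix(unclass(it0), "pna")
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.05)
})

test_that("missingness hits the calibrated rate and MNAR shifts observed means", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 100,
                    theta_pheno_selection = 0.8, target_missing_frac = 0.4,
                    n_causal = 20, seed = 131)
  g <- simulate_genotypes(cfg)
  tr <- simulate_nonresponse_factors(g, cfg)
  ph <- simulate_target_phenotype(g, tr, cfg)
  expect_equal(ph$selection$implied_missing_rate, 0.4, tolerance = 1e-6)
  expect_equal(mean(ph$missing), 0.4, tolerance = 0.02)
  # theta > 0 removes high phenotypes
  expect_lt(mean(ph$phenotype[ph$observed]), mean(ph$phenotype))
})

test_that("null-effect collider SNP acquires negative observed-data beta", {
  # alpha_j = 0, beta_j > 0, factor -> selection and phenotype -> selection:
  # conditioning on being observed makes the SNP predictive of low phenotype
  reps <- 30
  betas <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 8000, n_variants = 50, ld_rho = 0,
                      n_causal = 0, n_causal_nonresponse = 10,
                      h2_factor = 0.5, theta_pheno_selection = 1,
                      selection_factor_weight = 2,
                      eta_mediator_phenotype = 0, h2_phenotype = 0,
                      target_missing_frac = 0.4, seed = 140 + r)
    g <- simulate_genotypes(cfg)
    tr <- simulate_nonresponse_factors(g, cfg)
    ph <- simulate_target_phenotype(g, tr, cfg)
    j <- which.max(abs(tr$snp_effects_nonresponse))
    yobs <- ph$phenotype
    yobs[ph$missing] <- NA
    gw <- run_gwas(yobs, g)
    betas[r] <- gw$beta[match(g$variants$snp[j], gw$snp)] *
      sign(tr$snp_effects_nonresponse[j])
  }
  expect_lt(mean(betas), 0)
  expect_lt(t.test(betas)$p.value, 0.05)
})

test_that("follow-up participation responds to the nonresponse factors", {
  cfg <- sim_config(n_individuals = 20000, followup_intercept = 0.5,
                    followup_coef_pna = 0, followup_coef_idk = 0,
                    n_causal = 20, seed = 151)
  tr <- simulate_nonresponse_factors(simulate_genotypes(cfg), cfg)
  fu <- simulate_followup_participation(tr, cfg)
  expect_lt(abs(mean(fu$participation) - pnorm(0.5)), 0.015)

  cfg2 <- sim_config(n_individuals = 20000, followup_coef_pna = 0.5,
                     followup_coef_idk = 0, n_causal = 20, seed = 152)
  fu2 <- simulate_followup_participation(tr, cfg2)
  expect_lt(cor(fu2$participation, tr$general$pna), 0)
})

test_that("default follow-up preset yields its calibrated incremental pseudo-R2", {
  cfg <- sim_config(n_individuals = 50000, n_variants = 30, n_causal = 10,
                    seed = 155)
  tr <- simulate_nonresponse_factors(simulate_genotypes(cfg), cfg)
  fu <- simulate_followup_participation(tr, cfg)
  y <- 1 - fu$participation
  # oracle: likelihood of the generative probit model itself
  mu <- pnorm(-fu$linear_predictor)
  ll1 <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  oracle <- 1 - exp(2 * (ll0 - ll1) / length(y))
  got <- incremental_pseudo_r2(y, NULL, cbind(pna = tr$general$pna,
                                              idk = tr$general$idk))
  expect_equal(got, oracle, tolerance = 0.015)
  expect_gt(got, 0.035)
  expect_lt(got, 0.08)
})

test_that("the whole cohort is bit-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 500, n_variants = 40, n_items = 10,
                    n_causal = 10, seed = 161)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(unclass(a$items), unclass(b$items))
  expect_identical(a$pheno$phenotype, b$pheno$phenotype)
  expect_identical(a$followup$participation, b$followup$participation)
})
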