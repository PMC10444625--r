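# Heckman two-step machinery: probit stage, inverse Mills ratio and the
# corrected GWAS.

test_that("probit ML recovers generative coefficients", {
  set.seed(301)
  n <- 20000
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- as.numeric(runif(n) < pnorm(-0.2 + 0.5 * z1 - 0.3 * z2))
  fit <- probit_fit(y, cbind(z1, z2))
  expect_equal(unname(fit$gamma), c(-0.2, 0.5, -0.3), tolerance = 0.05)
  # agreement with the IRLS route in glm
  gl <- glm(y ~ z1 + z2, family = binomial(link = "probit"))
  expect_equal(unname(fit$gamma), unname(coef(gl)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(gl)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("intercept-only probit matches the closed form", {
  set.seed(302)
  y <- rbinom(5000, 1, 0.3)
  fit <- probit_fit(y, NULL)
  expect_equal(unname(fit$gamma), qnorm(mean(y)), tolerance = 1e-6)
})

test_that("degenerate and separated inputs raise errors", {
  expect_error(probit_fit(rep(0, 100), matrix(rnorm(100))), "degenerate")
  expect_error(probit_fit(rep(1, 100), NULL), "degenerate")
  x <- c(rnorm(50, -3), rnorm(50, 3))
  y <- rep(c(0, 1), each = 50)
  expect_error(probit_fit(y, matrix(x)), "separation|singular|converge")
})

test_that("inverse Mills ratio matches closed forms and is monotone", {
  expect_equal(inverse_mills(0), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(inverse_mills(1), dnorm(1) / pnorm(-1), tolerance = 1e-12)
  eta <- seq(-10, 10, by = 0.01)
  lam <- inverse_mills(eta)
  expect_true(all(diff(lam) > 0))
  expect_true(all(lam > 0))
  # tail behaviour: continuous across the asymptotic switch, ~eta at +inf
  expect_equal(inverse_mills(29.999), inverse_mills(30.001), tolerance = 1e-4)
  expect_equal(inverse_mills(50), 50 + 1 / 50, tolerance = 1e-3)
})

test_that("lambda coefficient sign opposes the direct selection path", {
  # theta < 0: low phenotypes go missing, observed residuals are right-
  # truncated, so the Mills-ratio coefficient is positive (and vice versa)
  run_one <- function(theta, seed) {
    cfg <- sim_config(n_individuals = 15000, n_variants = 50,
                      n_causal = 10, n_causal_nonresponse = 10,
                      theta_pheno_selection = theta,
                      selection_factor_weight = 1,
                      gamma_mediator_selection = 0.3,
                      eta_mediator_phenotype = 0.3,
                      h2_factor = 0.3, target_missing_frac = 0.4,
                      seed = seed)
    geno <- simulate_genotypes(cfg)
    tr <- simulate_nonresponse_factors(geno, cfg)
    ph <- simulate_target_phenotype(geno, tr, cfg)
    y <- ph$phenotype; y[ph$missing] <- NA
    hk <- heckman_gwas(y, geno, NULL,
                       cbind(f = tr$general$pna, z = ph$mediator),
                       response_extra = cbind(mediator = ph$mediator))
    c(hk$lambda_coef, hk$lambda_p)
  }
  neg <- run_one(-1, 311)
  expect_gt(neg[1], 0)
  expect_lt(neg[2], 1e-6)
  pos <- run_one(1, 312)
  expect_lt(pos[1], 0)
})

test_that("corrected and uncorrected GWAS agree when selection is uninformative", {
  aud <- heckman_bias_audit(preset_mcar(n_individuals = 8000,
                                        n_variants = 100),
                            n_reps = 6, seed = 321)
  # paired beta differences centred at zero
  d <- aud$betas$b_cor - aud$betas$b_unc
  expect_lt(abs(mean(d) / (sd(d) / sqrt(length(d)))), 4)
  expect_gt(aud$deming$slope + 3 * aud$deming$slope_se, 1)
  expect_lt(aud$deming$slope - 3 * aud$deming$slope_se, 1)
})

test_that("omitting the factor from the selection model degrades recovery", {
  # selection-model quality matters: dropping the nonresponse factor from
  # the probit stage increases mean absolute bias of corrected betas
  cfg <- preset_mnar(n_individuals = 12000, n_variants = 100)
  mab_full <- mab_drop <- numeric(4)
  for (r in 1:4) {
    cfg$seed <- 330L + r
    geno <- simulate_genotypes(cfg)
    tr <- simulate_nonresponse_factors(geno, cfg)
    ph <- simulate_target_phenotype(geno, tr, cfg)
    y <- ph$phenotype; y[ph$missing] <- NA
    med <- cbind(mediator = ph$mediator)
    full <- heckman_gwas(y, geno, NULL,
                         cbind(f = tr$general$pna, z = ph$mediator),
                         response_extra = med)
    drop <- heckman_gwas(y, geno, NULL, cbind(z = ph$mediator),
                         response_extra = med)
    ci <- match(geno$variants$snp[ph$causal_idx], full$corrected$snp)
    ok <- !is.na(ci); ci <- ci[ok]
    tv <- ph$true_beta[ph$causal_idx][ok]
    mab_full[r] <- mean(abs(full$corrected$beta[ci] - tv))
    mab_drop[r] <- mean(abs(drop$corrected$beta[ci] - tv))
  }
  expect_gt(mean(mab_drop), mean(mab_full))
})

test_that("collinear Mills ratio triggers the exclusion-restriction error", {
  set.seed(341)
  n <- 2000
  z <- rnorm(n)
  y <- rnorm(n) + z
  y[runif(n) < pnorm(-0.5 + 0.8 * z)] <- NA
  cfg <- sim_config(n_individuals = n, n_variants = 10, n_causal = 5,
                    seed = 342)
  geno <- simulate_genotypes(cfg)
  # selection model contains only the response covariate itself: lambda is
  # a function of it alone, and only its curvature separates them (R^2 of
  # lambda on z is ~0.91 here), so a 0.9 guard must fire
  expect_error(
    heckman_gwas(y, geno, NULL, cbind(z = z),
                 response_extra = cbind(z = z), collin_r2_max = 0.9),
    "collinear")
})

test_that("bootstrap lambda SE is of the same order as the naive SE", {
  cfg <- preset_mnar(n_individuals = 4000, n_variants = 50)
  cfg$seed <- 351L
  geno <- simulate_genotypes(cfg)
  tr <- simulate_nonresponse_factors(geno, cfg)
  ph <- simulate_target_phenotype(geno, tr, cfg)
  y <- ph$phenotype; y[ph$missing] <- NA
  Z <- cbind(f = tr$general$pna, z = ph$mediator)
  hk <- heckman_gwas(y, geno, NULL, Z,
                     response_extra = cbind(mediator = ph$mediator))
  bt <- heckman_lambda_bootstrap(y, cbind(mediator = ph$mediator), Z,
                                 n_boot = 60, seed = 352)
  expect_gt(bt$lambda_se_boot, hk$lambda_se / 5)
  expect_lt(bt$lambda_se_boot, hk$lambda_se * 5)
})
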