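# Follow-up prediction: logistic fits, pseudo-R2 measures, education
# recoding, order trend and the simple polygenic score.

test_that("logistic IRLS matches glm and the intercept closed form", {
  set.seed(401)
  n <- 20000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 1 * x1 - 0.5 * x2))
  fit <- logistic_fit(y, cbind(x1, x2))
  expect_equal(unname(fit$coefficients[2:3]), c(1, -0.5), tolerance = 0.05)
  gl <- glm(y ~ x1 + x2, family = binomial,
            control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(gl)), tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(summary(gl)$coefficients[, 2]), tolerance = 1e-6)

  f0 <- logistic_fit(rep(c(1, 0, 0, 0), 25))
  expect_equal(unname(f0$coefficients), log(1 / 3), tolerance = 1e-8)
  expect_error(logistic_fit(rep(1, 10)), "classes")
  expect_error(logistic_fit(rep(c(0, 1), each = 20),
                            matrix(c(rnorm(20, -5), rnorm(20, 5)))),
               "separation|converge")
})

test_that("all pseudo-R2 formulas match hand computation on a tiny dataset", {
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  x <- c(-1, 0.5, 0.2, 0.1, 1, -0.3, -2, 0.7)
  fit <- logistic_fit(y, matrix(x, dimnames = list(NULL, "x")))
  n <- 8
  cs_hand <- 1 - exp(2 * (fit$null_loglik - fit$loglik) / n)
  nk_hand <- cs_hand / (1 - exp(2 * fit$null_loglik / n))
  mz_hand <- var(fit$linear_predictor) /
    (var(fit$linear_predictor) + pi^2 / 3)
  expect_equal(pseudo_r2(fit, "cox_snell"), cs_hand, tolerance = 1e-10)
  expect_equal(pseudo_r2(fit, "nagelkerke"), nk_hand, tolerance = 1e-10)
  expect_equal(pseudo_r2(fit, "mckelvey_zavoina"), mz_hand, tolerance = 1e-10)
  expect_gte(pseudo_r2(fit, "nagelkerke"), pseudo_r2(fit, "cox_snell"))
  expect_error(pseudo_r2(fit, "banana"))
})

test_that("null fits give zero pseudo-R2 and nesting holds", {
  set.seed(411)
  y <- rbinom(500, 1, 0.4)
  f0 <- logistic_fit(y)
  expect_equal(pseudo_r2(f0, "cox_snell"), 0, tolerance = 1e-10)
  expect_equal(pseudo_r2(f0, "nagelkerke"), 0, tolerance = 1e-10)
  # noise increments are tiny; identical designs give exactly zero
  X <- matrix(rnorm(500), dimnames = list(NULL, "a"))
  expect_equal(incremental_pseudo_r2(y, X, X), 0, tolerance = 1e-12)
  noise <- cbind(X, b = rnorm(500))
  expect_lt(abs(incremental_pseudo_r2(y, X, noise)), 0.02)
  expect_error(incremental_pseudo_r2(y, noise, X), "nested")
})

test_that("incremental pseudo-R2 recovers a calibrated generative value", {
  set.seed(421)
  n <- 50000
  f1 <- rnorm(n); f2 <- rnorm(n)
  eta <- -1 + 0.35 * f1 + 0.4 * f2
  y <- rbinom(n, 1, plogis(eta))
  # oracle: evaluate the increment with the known generative coefficients
  mu <- plogis(eta)
  ll1 <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  oracle <- 1 - exp(2 * (ll0 - ll1) / n)
  got <- incremental_pseudo_r2(y, NULL, cbind(f1 = f1, f2 = f2))
  expect_equal(got, oracle, tolerance = 0.015)
  expect_gt(got, 0.03)

  # noise predictors converge to zero increment
  noise <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("n", 1:3)))
  expect_lt(incremental_pseudo_r2(y, cbind(f1 = f1, f2 = f2),
                                  cbind(f1 = f1, f2 = f2, noise)), 0.005)
})

test_that("education recoding reproduces the ISCED table", {
  expect_equal(recode_education("College or University degree")[1], 20L)
  expect_equal(recode_education("A levels/AS levels or equivalent")[1], 15L)
  expect_equal(recode_education("O levels/GCSEs or equivalent")[1], 13L)
  expect_equal(recode_education("CSE or equivalent")[1], 12L)
  expect_equal(recode_education("NVQ or HND or HNC or equivalent")[1], 19L)
  expect_equal(
    recode_education("Other professional qualifications eg: nursing, teaching")[1],
    17L)
  expect_equal(recode_education("None of the above")[1], 6L)
  # long-form phrasings map to the same years
  expect_equal(
    recode_education("Certificate of Secondary Education (CSE) or equivalent")[1],
    12L)
  out <- recode_education(c("Prefer not to answer", "None of the above"))
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "excluded"), c(TRUE, FALSE))
  expect_error(recode_education("Doctorate"), "unknown")
})

test_that("order trend test is calibrated and detects a real trend", {
  set.seed(431)
  flat <- rpois(100, 50)
  res <- order_trend_test(flat)
  expect_gt(res$p_positive_trend, 0.05)
  trended <- rnbinom(100, mu = 50 * exp(0.02 * (1:100)), size = 10)
  res2 <- order_trend_test(trended)
  expect_gt(res2$slope, 0.01)
  expect_lt(res2$slope, 0.03)
  expect_lt(res2$p_positive_trend, 0.01)
  # permuting order labels destroys the trend (most permutation p-values
  # are unremarkable)
  ps <- vapply(1:20, function(i) {
    order_trend_test(trended, order = sample(1:100))$p_positive_trend
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
  expect_error(order_trend_test(rep(0, 10)), "zero")
})

test_that("polygenic scores transfer association across cohorts", {
  # one generator run, disjoint training and scoring halves: the halves
  # share the generative SNP effects but no individuals
  cfg <- sim_config(n_individuals = 20000, n_variants = 200, ld_rho = 0,
                    n_causal = 200, n_causal_nonresponse = 0,
                    h2_factor = 0.3, seed = 441)
  g <- simulate_genotypes(cfg)
  tr <- simulate_nonresponse_factors(g, cfg)
  train <- 1:10000; test <- 10001:20000
  ga <- structure(list(dosage = g$dosage[train, ], variants = g$variants),
                  class = "genotype_matrix")
  gb <- structure(list(dosage = g$dosage[test, ], variants = g$variants),
                  class = "genotype_matrix")
  gw <- run_gwas(tr$general$pna[train], ga)
  w <- data.frame(snp = gw$snp, a1 = gw$a1, beta = gw$beta)
  prs <- simple_prs(gb, w)
  ct <- cor.test(prs, tr$general$pna[test], alternative = "greater")
  expect_lt(ct$p.value, 0.05)

  # degenerate weights and alignment errors
  expect_equal(attr(simple_prs(ga, rep(0, 200)), "raw"), rep(0, 10000))
  s1 <- simple_prs(ga, c(1, rep(0, 199)))
  expect_equal(cor(s1, ga$dosage[, 1]), 1, tolerance = 1e-12)
  w_bad <- w; w_bad$a1 <- "G"
  expect_error(simple_prs(gb, w_bad), "mismatch")
})
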