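# Factor construction: EFA, residual clustering, branch collapsing,
# bifactor CFA, variance decomposition and factor scores.

test_that("single-factor EFA recovers an exact one-factor model", {
  lam <- rep(0.7, 8)
  R <- tcrossprod(lam); diag(R) <- 1
  efa <- efa_single_factor(R)
  expect_equal(unname(efa$loadings[, 1]), lam, tolerance = 1e-6)
  expect_lt(max(abs(efa$residuals)), 1e-6)
  # identity input: nothing to extract
  efa0 <- efa_single_factor(diag(8))
  expect_lt(max(abs(efa0$loadings)), 1e-6)
})

test_that("single-factor residuals of bifactor data show domain blocks", {
  R <- bifactor_corr(seq(0.5, 0.7, length.out = 16), 0.5,
                     sort(rep(1:4, 4)))
  efa <- efa_single_factor(R)
  dom <- sort(rep(1:4, 4))
  same <- outer(dom, dom, "==") & upper.tri(R)
  diff <- outer(dom, dom, "!=") & upper.tri(R)
  expect_gt(mean(efa$residuals[same]), 0.05)
  expect_lt(mean(abs(efa$residuals[diff])), 0.05)
})

test_that("residual clustering finds block structure at any sensible cut", {
  # two perfectly correlated pairs + independent singletons
  res <- diag(0, 6)
  res[1, 2] <- res[2, 1] <- 0.9
  res[3, 4] <- res[4, 3] <- 0.9
  rownames(res) <- colnames(res) <- paste0("v", 1:6)
  br <- cluster_residuals(res, 0.5)
  expect_equal(length(unique(br$mapping)), 4)
  expect_equal(br$mapping[["v1"]], br$mapping[["v2"]])
  expect_equal(br$mapping[["v3"]], br$mapping[["v4"]])
  # cut at 0 -> all singletons
  expect_warning(br0 <- cluster_residuals(res, 0), "singleton")
  expect_equal(length(unique(br0$mapping)), 6)
})

test_that("clustering recovers generative domains from EFA residuals", {
  R <- bifactor_corr(seq(0.45, 0.7, length.out = 20), 0.5,
                     sort(rep(1:4, 5)))
  efa <- efa_single_factor(R)
  br <- cluster_residuals(efa$residuals, 0.9)
  expect_gt(adjusted_rand_index(br$mapping, sort(rep(1:4, 5))), 0.9)
})

test_that("branch collapsing applies the ordinal and sum rules exactly", {
  items <- rbind(c(-3, -3, -3, -3, -3),   # all PNA -> 3
                 c(-3,  0,  1,  2,  0),   # exactly one -> 1
                 c( 0,  4,  1,  2,  0),   # none -> 0
                 c(-3, -3,  1,  2,  0))   # two of five -> 2
  colnames(items) <- paste0("q", 1:5)
  map <- setNames(rep(1L, 5), colnames(items))
  ord <- collapse_branches(items, map, mode = "ordinal", response_code = "pna")
  expect_equal(unname(ord[, 1]), c(3L, 1L, 0L, 2L))
  # sum mode counts nonresponses
  idk <- rbind(c(-1, -1, 0, 7, 0), c(0, 0, 0, 0, 0))
  colnames(idk) <- paste0("q", 1:5)
  s <- collapse_branches(idk, map, mode = "sum", response_code = "idk")
  expect_equal(unname(s[, 1]), c(2L, 0L))
  # singleton branches pass the binary indicator through
  map2 <- setNames(c(1L, 2L, 2L, 2L, 2L), colnames(items))
  out <- collapse_branches(items, map2, mode = "ordinal", response_code = "pna")
  expect_equal(unname(out[, "br1"]), c(1L, 1L, 0L, 1L))
  expect_error(collapse_branches(items, setNames(integer(0), character(0))),
               "empty|branch")
})

test_that("sample splitting is disjoint, exhaustive and reproducible", {
  sp <- split_sample(10, 0.8, seed = 3)
  expect_equal(length(sp$first), 8)
  expect_equal(sort(c(sp$first, sp$second)), 1:10)
  expect_identical(split_sample(10, 0.8, seed = 3), sp)
  expect_error(split_sample(10, 1.2), "fraction")
})

test_that("bifactor EFA recovers generative loadings and is permutation-stable", {
  g <- seq(0.45, 0.75, length.out = 20)
  dom <- sort(rep(1:4, 5))
  R <- bifactor_corr(g, 0.5, dom)
  efa <- efa_bifactor(R, 4)
  expect_gt(cor(efa$loadings[, 1], g), 0.99)
  pat <- bifactor_pattern(efa)
  expect_gt(adjusted_rand_index(max.col(pat * 1), dom), 0.99)

  # permuting items permutes loadings identically
  perm <- c(11:20, 1:10)
  efa_p <- efa_bifactor(R[perm, perm], 4)
  expect_equal(abs(unname(efa_p$loadings[, 1])),
               abs(unname(efa$loadings[perm, 1])), tolerance = 1e-4)

  # no group structure in truth: group factors absorb little variance
  R1 <- tcrossprod(rep(0.6, 12)); diag(R1) <- 1
  efa1 <- efa_bifactor(R1, 2)
  expect_lt(sum(efa1$loadings[, -1]^2) / 12, 0.05)
})

test_that("bifactor CFA reproduces an exact generative model", {
  g <- seq(0.5, 0.7, length.out = 16)
  dom <- sort(rep(1:4, 4))
  R <- bifactor_corr(g, 0.5, dom)
  pat <- matrix(FALSE, 16, 4)
  pat[cbind(1:16, dom)] <- TRUE
  fit <- cfa_bifactor(R, pat, n_obs = 5000)
  expect_lt(max(abs(fit$general_loadings - g)), 1e-3)
  expect_lt(max(abs(fit$group_loadings[pat] - 0.5)), 1e-3)
  expect_lt(fit$fit$rmsea, 0.01)
  expect_lt(fit$fit$srmr, 1e-3)

  # a strictly coarser (misspecified) pattern fits worse
  pat_bad <- matrix(FALSE, 16, 2)
  pat_bad[, 1] <- dom %in% c(1, 2)
  pat_bad[, 2] <- dom %in% c(3, 4)
  fit_bad <- cfa_bifactor(R, pat_bad, n_obs = 5000)
  expect_gt(fit_bad$fit$discrepancy, fit$fit$discrepancy)
  expect_gt(fit_bad$fit$rmsea, fit$fit$rmsea)
})

test_that("CFA flags saturation and unidentified patterns", {
  R3 <- tcrossprod(c(0.6, 0.7, 0.5)); diag(R3) <- 1
  fit <- cfa_bifactor(R3, matrix(logical(0), 3, 0), n_obs = 1000)
  expect_true(fit$fit$saturated)
  expect_equal(fit$fit$df, 0)
  expect_lt(fit$fit$discrepancy, 1e-10)
  pat <- matrix(FALSE, 3, 1); pat[1:2, 1] <- TRUE
  expect_error(cfa_bifactor(diag(3), pat, n_obs = 100), "3 items")
})

test_that("variance decomposition follows the squared-loading identity", {
  g <- rep(0.7, 10)
  R <- tcrossprod(g); diag(R) <- 1
  fit <- cfa_bifactor(R, matrix(logical(0), 10, 0), n_obs = 1000)
  ve <- variance_explained(fit)
  expect_equal(ve$general_pct, 49, tolerance = 0.1)
  expect_equal(ve$group_pct, 0)
  expect_lte(ve$general_pct + ve$group_pct, 100)
})

test_that("factor scores are monotone, deterministic and track the truth", {
  set.seed(55)
  cfg <- sim_config(n_individuals = 8000, n_items = 40, n_domains = 4,
                    general_loading = 0.6, domain_loading = 0.5,
                    item_threshold_range = c(0.8, 1.8), n_causal = 20,
                    seed = 171)
  co <- simulate_cohort(cfg)
  ind <- (unclass(co$items) == -3) * 1L
  colnames(ind) <- colnames(co$items)
  R <- tetrachoric_matrix(ind, "binary")
  efa <- efa_bifactor(R, 4)
  fit <- cfa_bifactor(R, bifactor_pattern(efa), n_obs = nrow(ind), start = efa)
  sc <- factor_scores(ind, fit)
  expect_gt(cor(sc$general, co$truth$general$pna), 0.7)
  # all-zero rows get the cohort minimum; identical rows identical scores
  zero_rows <- which(rowSums(ind) == 0)
  expect_equal(min(sc$general), unique(round(sc$general[zero_rows], 10)))
  i2 <- which(duplicated(ind) | duplicated(ind, fromLast = TRUE))
  if (length(i2) >= 2) {
    key <- apply(ind[i2, ], 1, paste, collapse = "")
    grp <- split(sc$general[i2], key)
    expect_true(all(vapply(grp, function(v) diff(range(v)) < 1e-10, logical(1))))
  }
})
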