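# Confirmatory bifactor factor analysis by unweighted least squares, plus
# variance decomposition and latent-liability factor scores.

#' Polychoric/tetrachoric correlation matrix of mixed ordinal indicators
#'
#' For collapsed branch indicators: columns with few observed levels
#' (<= `max_levels`) get two-step ML polychoric correlations (tetrachoric
#' when binary); columns with many levels (e.g. long IDK count scales) fall
#' back to the Pearson correlation. The result is PSD-repaired.
#'
#' @param X integer matrix of ordinal indicators.
#' @param max_levels largest level count treated as ordinal.
#' @return correlation matrix with attribute `psd_projection_norm`.
#' @export
polychoric_matrix <- function(X, max_levels = 8) {
  X <- as.matrix(X)
  q <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(q))
  nlev <- apply(X, 2, function(x) length(unique(x)))
  keep <- nlev >= 2
  if (any(!keep))
    warning("dropping constant indicators: ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  nlev <- nlev[keep]
  q <- ncol(X)
  if (q < 2) stop("need at least 2 non-constant indicators")
  R <- diag(1, q)
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      R[i, j] <- R[j, i] <-
        if (nlev[i] <= max_levels && nlev[j] <= max_levels)
          polychoric_rho(X[, i], X[, j])$rho
        else
          cor(X[, i], X[, j])
    }
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  nearest_psd(R)
}

#' Confirmatory bifactor model by unweighted least squares
#'
#' Fits `Sigma = L L' + Psi` with `L = [g | Gamma]`: a general factor
#' loading on every item and orthogonal group factors whose free loadings
#' are given by `pattern` (zeros are respected exactly). The discrepancy
#' `F = sum_{i<j} (r_ij - sigma_ij)^2` is minimized; uniquenesses absorb the
#' diagonal. Fit indices are ULS analogues computed from the discrepancy
#' and degrees of freedom (`T = (n_obs - 1) F`, independence-model null).
#'
#' @param corr correlation matrix (typically the holdout sample).
#' @param pattern logical items x groups matrix of free group loadings; a
#'   zero-column matrix fits the general factor alone.
#' @param n_obs number of observations behind `corr` (for fit indices).
#' @param start optional `"efa_result"` supplying start values.
#' @return object of class `"bifactor_model"`: `general_loadings`,
#'   `group_loadings` (sparse, zeros where constrained), `uniquenesses`,
#'   `pattern`, `fit` (list: discrepancy, df, rmsea, tli, srmr, n_obs,
#'   saturated flag), `variance_explained`.
#' @export
cfa_bifactor <- function(corr, pattern, n_obs, start = NULL) {
  R <- as.matrix(corr)
  p <- ncol(R)
  pattern <- as.matrix(pattern)
  if (nrow(pattern) != p) stop("pattern rows must match items")
  k <- ncol(pattern)
  if (k > 0 && any(colSums(pattern) < 3))
    stop("unidentified pattern: every group factor needs >= 3 items")
  npar <- p + sum(pattern)
  ndist <- p * (p - 1) / 2
  df <- ndist - npar
  if (df < 0) stop("model has negative degrees of freedom (", npar,
                   " free loadings, ", ndist, " correlations)")

  idx_g <- seq_len(p)
  idx_s <- which(pattern)
  unpack <- function(th) {
    L <- matrix(0, p, k + 1)
    L[, 1] <- th[idx_g]
    if (k > 0) L[, -1][idx_s] <- th[p + seq_along(idx_s)]
    L
  }
  ut <- upper.tri(R)
  obj <- function(th) {
    L <- unpack(th)
    S <- tcrossprod(L)
    h2 <- diag(S)
    sum((R[ut] - S[ut])^2) + 100 * sum(pmax(h2 - 1, 0)^2)
  }
  th0 <- if (!is.null(start)) {
    Ls <- start$loadings
    gs <- Ls[, 1]
    ss <- if (k > 0) pmax(pmin(abs(Ls[, -1, drop = FALSE][idx_s]), 0.9), 0.1)
          else numeric(0)
    c(pmax(pmin(gs, 0.95), -0.95), ss)
  } else c(rep(0.5, p), rep(0.4, length(idx_s)))
  fit <- nlminb(th0, obj, lower = -0.999, upper = 0.999,
                control = list(iter.max = 2000, eval.max = 4000))
  L <- unpack(fit$par)
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, `*`)
  S <- tcrossprod(L)
  res <- R - S
  Fmin <- sum(res[ut]^2)
  srmr <- sqrt(Fmin / ndist)
  F0 <- sum(R[ut]^2)
  Tstat <- (n_obs - 1) * Fmin
  T0 <- (n_obs - 1) * F0
  saturated <- df == 0
  rmsea <- if (saturated) 0 else sqrt(max(0, (Tstat - df) / (df * (n_obs - 1))))
  tli <- if (saturated) 1 else {
    num <- T0 / ndist - Tstat / df
    den <- T0 / ndist - 1
    if (abs(den) < 1e-12) 1 else num / den
  }
  gl <- L[, 1]
  names(gl) <- rownames(R)
  Gamma <- L[, -1, drop = FALSE]
  rownames(Gamma) <- rownames(R)
  colnames(Gamma) <- colnames(pattern)
  uni <- pmax(1 - rowSums(L^2), 0)
  ve <- list(general_pct = sum(gl^2) / p * 100,
             group_pct = sum(Gamma^2) / p * 100)
  structure(list(general_loadings = gl, group_loadings = Gamma,
                 uniquenesses = uni, pattern = pattern,
                 fit = list(discrepancy = Fmin, df = df, rmsea = rmsea,
                            tli = tli, srmr = srmr, n_obs = n_obs,
                            saturated = saturated,
                            converged = fit$convergence == 0),
                 variance_explained = ve),
            class = "bifactor_model")
}

#' @export
print.bifactor_model <- function(x, ...) {
  cat(sprintf(
    "bifactor CFA (ULS): %d items, %d group factor(s)\n  RMSEA %.4f, TLI %.3f, SRMR %.4f (df %d%s)\n  variance explained: general %.2f%%, group %.2f%%\n",
    length(x$general_loadings), ncol(x$group_loadings),
    x$fit$rmsea, x$fit$tli, x$fit$srmr, x$fit$df,
    if (x$fit$saturated) ", saturated" else "",
    x$variance_explained$general_pct, x$variance_explained$group_pct),
    ...)
  invisible(x)
}

#' Variance explained by the general and group factors
#'
#' Percentage of total indicator variance attributable to the general
#' factor (`sum of squared general loadings / n_items * 100`) and to the
#' group factors.
#'
#' @param model a [cfa_bifactor()] result.
#' @return list with `general_pct` and `group_pct`.
#' @export
variance_explained <- function(model) model$variance_explained

#' Latent-liability factor scores (regression / posterior-mean method)
#'
#' Empirical-Bayes style scores under the multivariate-normal liability
#' approximation: each ordinal indicator is replaced by the conditional
#' mean of its latent liability given the observed category (thresholds
#' from the marginal category proportions), then the regression-method
#' posterior mean `E[f | x] = L' Sigma^{-1} x` is applied with the fitted
#' loadings. Scores are standardized before downstream association work.
#'
#' @param indicators integer matrix the model was fitted to (same columns).
#' @param model a [cfa_bifactor()] result.
#' @return object of class `"factor_scores"`: list with `general`
#'   (standardized N-vector), `group` (N x k matrix), `method`.
#' @export
factor_scores <- function(indicators, model) {
  X <- as.matrix(indicators)
  p <- length(model$general_loadings)
  if (ncol(X) != p) stop("indicator columns do not match the fitted model")
  if (anyNA(X)) stop("missing indicator values are not supported")
  n <- nrow(X)
  # conditional liability mean per observed category
  Xt <- matrix(0, n, p)
  for (j in seq_len(p)) {
    x <- X[, j]
    lev <- sort(unique(x))
    pr <- cumsum(tabulate(match(x, lev), length(lev))) / n
    tau <- qnorm(pmin(pmax(pr[-length(pr)], 1e-10), 1 - 1e-10))
    a <- c(-Inf, tau)[match(x, lev)]
    b <- c(tau, Inf)[match(x, lev)]
    Xt[, j] <- (dnorm(a) - dnorm(b)) / pmax(pnorm(b) - pnorm(a), 1e-12)
  }
  L <- cbind(model$general_loadings, model$group_loadings)
  S <- tcrossprod(L) + diag(pmax(model$uniquenesses, 0.02), p)
  W <- solve(S, L)                      # p x (k+1)
  sc <- Xt %*% W
  general <- as.vector(scale(sc[, 1]))
  group <- sc[, -1, drop = FALSE]
  if (ncol(group) > 0) group <- scale(group)
  structure(list(general = general, group = group,
                 method = "regression (liability posterior mean)"),
            class = "factor_scores")
}

#' Full phenotype-construction pipeline for one response type
#'
#' Composes the construction stages: tetrachoric matrix of nonresponse
#' indicators on the EFA split, single-factor EFA, residual clustering at
#' `cut_height`, branch collapsing (ordinal for PNA, sums for IDK),
#' polychoric correlation of the collapsed indicators, bifactor EFA,
#' pattern derivation, holdout CFA, refit on the full sample and factor
#' scores.
#'
#' @param items coded item matrix (codes -3 / -1 / substantive).
#' @param response `"pna"` or `"idk"`.
#' @param cut_height residual dendrogram cut (defaults 0.500 for PNA,
#'   0.775 for IDK).
#' @param n_group_factors group factors in the bifactor model (defaults 5
#'   for PNA, 4 for IDK).
#' @param efa_fraction EFA split fraction (default 0.8).
#' @param seed split seed.
#' @return list with `scores` ([factor_scores()]), `model` (full-sample
#'   CFA), `holdout_fit` (holdout CFA fit indices), `efa1`, `efa_bi`,
#'   `branches`, `collapsed`.
#' @export
construct_nonresponse_factors <- function(items, response = c("pna", "idk"),
                                          cut_height = NULL,
                                          n_group_factors = NULL,
                                          efa_fraction = 0.8, seed = 1L) {
  response <- match.arg(response)
  if (is.null(cut_height)) cut_height <- if (response == "pna") 0.500 else 0.775
  if (is.null(n_group_factors)) n_group_factors <- if (response == "pna") 5L else 4L
  X <- as.matrix(items)
  n <- nrow(X)
  sp <- split_sample(n, efa_fraction, seed = seed)

  R1 <- tetrachoric_matrix(X[sp$first, , drop = FALSE], response)
  efa1 <- efa_single_factor(R1)
  branches <- cluster_residuals(efa1$residuals, cut_height)
  collapsed <- collapse_branches(X, branches,
                                 mode = if (response == "pna") "ordinal" else "sum",
                                 response_code = response)
  # keep indicators that vary within both splits so every stage sees the
  # same columns
  ok <- apply(collapsed[sp$first, , drop = FALSE], 2, function(x) length(unique(x)) > 1) &
        apply(collapsed[sp$second, , drop = FALSE], 2, function(x) length(unique(x)) > 1)
  bi <- attr(collapsed, "branch_items")
  collapsed <- collapsed[, ok, drop = FALSE]
  attr(collapsed, "branch_items") <- bi[ok]
  Rc_efa <- polychoric_matrix(collapsed[sp$first, , drop = FALSE])
  efa_bi <- efa_bifactor(Rc_efa, n_group_factors)
  pattern <- bifactor_pattern(efa_bi)
  Rc_hold <- polychoric_matrix(collapsed[sp$second, , drop = FALSE])
  hold <- cfa_bifactor(Rc_hold, pattern, n_obs = length(sp$second),
                       start = efa_bi)
  Rc_full <- polychoric_matrix(collapsed)
  model <- cfa_bifactor(Rc_full, pattern, n_obs = n, start = efa_bi)
  scores <- factor_scores(collapsed, model)
  list(scores = scores, model = model, holdout_fit = hold$fit,
       efa1 = efa1, efa_bi = efa_bi, branches = branches,
       collapsed = collapsed)
}
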