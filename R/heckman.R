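# Two-step Heckman correction for GWAS under informative missingness.
#
# Stage 1: probit model of the missingness indicator on selection
# covariates (nonresponse factor scores, mediators, demographics); the
# inverse Mills ratio of the predicted missingness liability is computed
# for the observed individuals. Stage 2: the GWAS response model includes
# that ratio as an extra covariate, conditioning the expected observed
# phenotype on the likelihood of selection.

#' Maximum-likelihood probit regression (Newton-Raphson)
#'
#' @param miss_indicator 0/1 vector (1 = phenotype missing).
#' @param Z covariate matrix (an intercept column is added).
#' @param tol convergence tolerance on the score norm.
#' @param max_iter iteration cap.
#' @return object of class `"selection_model"`: list with `gamma`
#'   (coefficients incl. intercept), `se`, `linear_predictor` (full cohort),
#'   `loglik`, `null_loglik`, `pseudo_r2` (McFadden), `converged`, `n`.
#' @export
probit_fit <- function(miss_indicator, Z = NULL, tol = 1e-8, max_iter = 50) {
  y <- as.numeric(miss_indicator)
  if (!all(y %in% c(0, 1))) stop("miss_indicator must be 0/1")
  if (length(unique(y)) < 2)
    stop("degenerate outcome: both response classes must be present")
  X <- if (is.null(Z)) matrix(1, length(y), 1) else cbind(1, as.matrix(Z))
  colnames(X) <- c("(Intercept)",
                   if (ncol(X) > 1) {
                     nm <- colnames(X)[-1]
                     if (is.null(nm) || any(nm == "")) paste0("z", seq_len(ncol(X) - 1)) else nm
                   })
  if (qr(X)$rank < ncol(X)) stop("selection covariates are rank deficient")
  n <- length(y)
  b <- qr.solve(crossprod(X) + diag(1e-8, ncol(X)),
                crossprod(X, qnorm((sum(y) + 0.5) / (n + 1)) + (y - mean(y))))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(pnorm(eta, log.p = TRUE) * y + pnorm(-eta, log.p = TRUE) * (1 - y))
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    # score and observed information of the probit likelihood
    phi <- dnorm(eta)
    Phi <- pnorm(eta)
    Phi <- pmin(pmax(Phi, 1e-12), 1 - 1e-12)
    u <- phi * (y - Phi) / (Phi * (1 - Phi))
    score <- crossprod(X, u)
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    w <- phi^2 / (Phi * (1 - Phi))
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e)
      stop("probit information matrix is singular (possible separation)"))
    # step-halving to keep the likelihood increasing
    ll0 <- loglik(b)
    s <- 1
    repeat {
      b_new <- b + s * step
      if (loglik(b_new) >= ll0 - 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    b <- b_new
    if (max(abs(drop(X %*% b))) > 35)
      stop("complete separation: probit linear predictor diverged")
  }
  if (!converged) stop("probit did not converge in ", max_iter, " iterations")
  eta <- drop(X %*% b)
  mu_chk <- pnorm(eta)
  if (all(pmin(mu_chk, 1 - mu_chk) < 1e-8))
    stop("complete separation: every observation is classified perfectly")
  phi <- dnorm(eta); Phi <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
  w <- phi^2 / (Phi * (1 - Phi))
  V <- solve(crossprod(X * w, X))
  ll1 <- loglik(b)
  ll0 <- sum(log(mean(y)) * y + log(1 - mean(y)) * (1 - y))
  structure(list(gamma = setNames(drop(b), colnames(X)),
                 se = setNames(sqrt(diag(V)), colnames(X)),
                 vcov = V,
                 linear_predictor = eta,
                 loglik = ll1, null_loglik = ll0,
                 pseudo_r2 = 1 - ll1 / ll0,
                 converged = converged, n = n),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("probit selection model: n = %d, McFadden pseudo-R2 = %.4f\n",
              x$n, x$pseudo_r2))
  print(round(cbind(gamma = x$gamma, se = x$se), 4))
  invisible(x)
}

#' Inverse Mills ratio of a missingness liability
#'
#' `lambda(eta) = phi(eta) / Phi(-eta)`, the standard-normal hazard of the
#' predicted missingness liability, strictly increasing in `eta`. The
#' direct ratio is numerically stable for `eta <= 30`; beyond that the
#' asymptotic expansion `eta + 1/eta - 2/eta^3` is used.
#'
#' @param model a [probit_fit()] result, or a numeric vector of liabilities.
#' @return numeric vector of positive values.
#' @examples
#' inverse_mills(0)  # sqrt(2/pi)
#' @export
inverse_mills <- function(model) {
  eta <- if (inherits(model, "selection_model")) model$linear_predictor
         else as.numeric(model)
  out <- numeric(length(eta))
  hi <- eta > 30
  out[!hi] <- dnorm(eta[!hi]) / pnorm(-eta[!hi])
  out[hi] <- eta[hi] + 1 / eta[hi] - 2 / eta[hi]^3
  out
}

#' Heckman two-step corrected GWAS
#'
#' Fits the probit selection model for missingness on the full cohort,
#' computes the inverse Mills ratio of the predicted missingness liability
#' for observed individuals, and re-runs the GWAS with that ratio as an
#' additional response-model covariate. The ratio's own coefficient is
#' variant-independent and reported once from the genotype-free response
#' model. Second-stage standard errors are naive OLS (see
#' [heckman_lambda_bootstrap()] for resampled SEs).
#'
#' @param phenotype numeric vector with NAs where missing.
#' @param genotypes a `genotype_matrix`.
#' @param covars response-model [covariate_design()] (or NULL).
#' @param selection_covars matrix/data.frame of selection covariates for
#'   the full cohort (should include the nonresponse factor scores; must
#'   contain at least one variable excluded from the response design,
#'   otherwise the Mills ratio is close to collinear with the response
#'   covariates).
#' @param response_extra optional matrix of additional response-model
#'   covariates aligned to the full cohort (e.g. outcome-relevant
#'   mediators that also sit in the selection model).
#' @param collin_r2_max collinearity guard: error if the R-squared of the
#'   Mills ratio on the other response covariates exceeds this (default
#'   0.999), the symptom of a selection model with no exclusion
#'   restriction.
#' @return list with `corrected` (`gwas_result`), `uncorrected`
#'   (`gwas_result`), `selection` (the `selection_model`), `lambda`
#'   (observed-individual Mills ratios), `lambda_coef`, `lambda_se`,
#'   `lambda_p`.
#' @export
heckman_gwas <- function(phenotype, genotypes, covars, selection_covars,
                         response_extra = NULL, collin_r2_max = 0.999) {
  miss <- as.numeric(is.na(phenotype))
  sel <- probit_fit(miss, selection_covars)
  lambda_all <- inverse_mills(sel)
  obs <- !is.na(phenotype)
  re <- if (!is.null(response_extra)) as.matrix(response_extra)

  # response design collinearity check (lambda vs covariates)
  Xr <- cbind(1, if (!is.null(covars)) unclass(covars)[obs, , drop = FALSE],
              if (!is.null(re)) re[obs, , drop = FALSE],
              lambda = lambda_all[obs])
  # the guard only applies when the selection stage carries signal: with an
  # uninformative probit the ratio is near-constant and harmless, even
  # though its residual variation is linearly spanned by the covariates
  lam_o <- Xr[, ncol(Xr)]
  if (ncol(Xr) > 2 && sel$pseudo_r2 > 1e-3) {
    res_l <- lm.fit(Xr[, -ncol(Xr), drop = FALSE], lam_o)$residuals
    r2_l <- 1 - sum(res_l^2) / sum((lam_o - mean(lam_o))^2)
    if (r2_l > collin_r2_max)
      stop("inverse Mills ratio is collinear with response covariates; ",
           "add exclusion-restriction variables to the selection model")
  }

  uncorrected <- run_gwas(phenotype, genotypes, covars, extra_covars = re)
  corrected <- run_gwas(phenotype, genotypes, covars,
                        extra_covars = cbind(
                          re, lambda = lambda_all))
  # lambda coefficient from the genotype-free response model
  yo <- phenotype[obs]
  fit <- lm.fit(Xr, yo)
  rss <- sum(fit$residuals^2)
  dfres <- length(yo) - fit$rank
  XtXi <- chol2inv(chol(crossprod(Xr)))
  lam_idx <- ncol(Xr)
  lam_se <- sqrt(rss / dfres * XtXi[lam_idx, lam_idx])
  lam_coef <- fit$coefficients[lam_idx]
  lam_p <- 2 * pt(abs(lam_coef / lam_se), df = dfres, lower.tail = FALSE)
  list(corrected = corrected, uncorrected = uncorrected,
       selection = sel, lambda = lambda_all[obs],
       lambda_coef = unname(lam_coef), lambda_se = lam_se, lambda_p = lam_p)
}

#' Bootstrap SE for the response-model lambda coefficient
#'
#' Nonparametric bootstrap over individuals, re-running both Heckman stages
#' per replicate; accounts for the first-stage estimation of lambda, which
#' the naive OLS standard error ignores.
#'
#' @param phenotype,covars,selection_covars as in [heckman_gwas()].
#' @param n_boot replicates.
#' @param seed RNG seed.
#' @return list with `lambda_se_boot` and the replicate vector.
#' @export
heckman_lambda_bootstrap <- function(phenotype, covars, selection_covars,
                                     n_boot = 200, seed = 1L) {
  set.seed(seed)
  n <- length(phenotype)
  Zs <- as.matrix(selection_covars)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    ph <- phenotype[idx]
    if (all(is.na(ph)) || !any(is.na(ph))) return(NA_real_)
    sel <- tryCatch(probit_fit(as.numeric(is.na(ph)), Zs[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sel)) return(NA_real_)
    lam <- inverse_mills(sel)
    obs <- !is.na(ph)
    Xr <- cbind(1, if (!is.null(covars)) unclass(covars)[idx, , drop = FALSE][obs, , drop = FALSE],
                lam[obs])
    fit <- lm.fit(Xr, ph[obs])
    fit$coefficients[ncol(Xr)]
  }, numeric(1))
  list(lambda_se_boot = sd(reps, na.rm = TRUE), replicates = reps)
}
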