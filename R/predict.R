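# Prediction of follow-up nonresponse and participation: logistic
# regression via IRLS, pseudo-R2 measures, education recoding and the
# question-order trend test.

#' Maximum-likelihood logistic regression (IRLS)
#'
#' @param y binary 0/1 outcome.
#' @param X covariate matrix (intercept added).
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter iteration cap.
#' @return object of class `"logistic_fit"`: `coefficients`, `se`,
#'   `loglik`, `null_loglik`, `fitted` (probabilities), `linear_predictor`,
#'   `n`, `X` (design without intercept).
#' @export
logistic_fit <- function(y, X = NULL, tol = 1e-8, max_iter = 100) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  D <- if (is.null(X)) matrix(1, length(y), 1) else cbind(1, as.matrix(X))
  colnames(D) <- c("(Intercept)",
                   if (ncol(D) > 1) {
                     nm <- colnames(D)[-1]
                     if (is.null(nm) || any(nm == "")) paste0("x", seq_len(ncol(D) - 1)) else nm
                   })
  if (qr(D)$rank < ncol(D)) stop("design is rank deficient")
  n <- length(y)
  b <- rep(0, ncol(D))
  b[1] <- qlogis(mean(y))
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12))
      stop("separation: fitted probabilities at the boundary")
    z <- eta + (y - mu) / w
    b_new <- qr.solve(D * sqrt(w), sqrt(w) * z)
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- b_new
    if (it == max_iter) stop("IRLS did not converge in ", max_iter, " iterations")
  }
  eta <- drop(D %*% b)
  mu <- plogis(eta)
  V <- solve(crossprod(D * sqrt(mu * (1 - mu))))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  structure(list(coefficients = setNames(drop(b), colnames(D)),
                 se = setNames(sqrt(diag(V)), colnames(D)),
                 loglik = ll, null_loglik = ll0,
                 fitted = mu, linear_predictor = eta, n = n,
                 X = if (is.null(X)) NULL else as.matrix(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  cat(sprintf("logistic fit: n = %d, loglik = %.2f (null %.2f)\n",
              x$n, x$loglik, x$null_loglik))
  print(round(cbind(estimate = x$coefficients, se = x$se,
                    p = 2 * pnorm(-abs(z))), 4))
  invisible(x)
}

#' Pseudo-R2 for a fitted logistic model
#'
#' Cox-Snell: `1 - exp(2 * (ll0 - ll1) / n)`. Nagelkerke rescales
#' Cox-Snell by its maximum `1 - exp(2 * ll0 / n)`. McKelvey-Zavoina works
#' on the latent scale: `var(X b) / (var(X b) + pi^2 / 3)` for the logit
#' link (`link = "probit"` substitutes residual variance 1, for selection
#' models).
#'
#' @param fit a [logistic_fit()].
#' @param method `"cox_snell"`, `"nagelkerke"` or `"mckelvey_zavoina"`.
#' @param link latent residual scale for McKelvey-Zavoina.
#' @return single numeric value.
#' @export
pseudo_r2 <- function(fit, method = c("cox_snell", "nagelkerke",
                                      "mckelvey_zavoina"),
                      link = c("logit", "probit")) {
  method <- match.arg(method)
  link <- match.arg(link)
  n <- fit$n
  cs <- 1 - exp(2 * (fit$null_loglik - fit$loglik) / n)
  switch(method,
         cox_snell = cs,
         nagelkerke = cs / (1 - exp(2 * fit$null_loglik / n)),
         mckelvey_zavoina = {
           v <- var(fit$linear_predictor)
           resid_var <- if (link == "logit") pi^2 / 3 else 1
           v / (v + resid_var)
         })
}

#' Incremental pseudo-R2 of added predictors
#'
#' Fits nested logistic models and returns
#' `pseudo_r2(full) - pseudo_r2(base)`. `X_base` columns must be a subset
#' of `X_full` columns (by name if named, by position otherwise).
#'
#' @param y binary outcome.
#' @param X_base,X_full design matrices (NULL base = intercept-only).
#' @param method passed to [pseudo_r2()].
#' @return single numeric value (>= 0 up to numerical tolerance for ML
#'   fits of nested models, Cox-Snell/Nagelkerke).
#' @export
incremental_pseudo_r2 <- function(y, X_base, X_full,
                                  method = c("cox_snell", "nagelkerke",
                                             "mckelvey_zavoina")) {
  method <- match.arg(method)
  Xf <- as.matrix(X_full)
  if (!is.null(X_base)) {
    Xb <- as.matrix(X_base)
    nested <- if (!is.null(colnames(Xb)) && !is.null(colnames(Xf)))
      all(colnames(Xb) %in% colnames(Xf))
    else ncol(Xb) <= ncol(Xf) &&
      all(vapply(seq_len(ncol(Xb)), function(j)
        any(apply(Xf, 2, function(col) isTRUE(all.equal(col, Xb[, j])))),
        logical(1)))
    if (!nested) stop("designs are not nested: X_base must be contained in X_full")
  }
  f1 <- logistic_fit(y, X_base)
  f2 <- logistic_fit(y, Xf)
  pseudo_r2(f2, method) - pseudo_r2(f1, method)
}

# UKB qualification -> years of education (ISCED-based recoding)
.edu_table <- c(
  "college or university degree" = 20L,
  "a levels/as levels or equivalent" = 15L,
  "o levels/gcses or equivalent" = 13L,
  "cse or equivalent" = 12L,
  "nvq or hnd or hnc or equivalent" = 19L,
  "other professional qualifications eg: nursing, teaching" = 17L,
  "none of the above" = 6L)
.edu_aliases <- c(
  "advanced (a) levels/advanced subsidiary (as) levels or equivalent" =
    "a levels/as levels or equivalent",
  "ordinary (o) levels/general certificate of secondary education (gcse) or equivalent" =
    "o levels/gcses or equivalent",
  "certificate of secondary education (cse) or equivalent" =
    "cse or equivalent",
  "national vocational qualification (nvq) or higher national diploma (hnd) or higher national certificate (hnc) or equivalent" =
    "nvq or hnd or hnc or equivalent",
  "other professional qualification (for example, nursing, teaching)" =
    "other professional qualifications eg: nursing, teaching",
  "other professional qualifications" =
    "other professional qualifications eg: nursing, teaching")

#' Recode UKB qualification categories to years of education
#'
#' ISCED-based mapping: degree = 20, A/AS levels = 15, O levels/GCSE = 13,
#' CSE = 12, NVQ/HND/HNC = 19, other professional = 17, none of the
#' above = 6. Matching is case-insensitive and tolerates the common
#' long-form phrasings. Nonresponse categories ("Prefer not to answer",
#' "I don't know", codes -3/-1) yield `NA` with attribute `excluded`,
#' signalling exclusion rather than a value.
#'
#' @param qualification character (or numeric code) vector.
#' @return integer vector of years; attribute `excluded` flags nonresponse
#'   entries.
#' @export
recode_education <- function(qualification) {
  q <- tolower(trimws(as.character(qualification)))
  excluded <- q %in% c("prefer not to answer", "i don't know", "-3", "-1")
  canon <- ifelse(q %in% names(.edu_aliases), .edu_aliases[q], q)
  known <- canon %in% names(.edu_table) | excluded
  if (any(!known))
    stop("unknown qualification category: ",
         paste(unique(qualification[!known]), collapse = "; "))
  out <- rep(NA_integer_, length(q))
  out[!excluded] <- .edu_table[canon[!excluded]]
  attr(out, "excluded") <- excluded
  out
}

#' Question-order trend test for nonresponse counts
#'
#' Negative-binomial regression (log link, ML dispersion) of per-question
#' nonresponse counts on presentation order, testing the fatigue
#' hypothesis that nonresponse grows with question position. Reports the
#' two-sided Wald p and the one-sided p for a positive trend.
#'
#' @param nonresponse_counts non-negative integer vector (one per question).
#' @param order question rank (default: position).
#' @param exposure optional participants-at-risk offset.
#' @return list with `slope`, `se`, `p_two_sided`, `p_positive_trend`,
#'   `dispersion`.
#' @export
order_trend_test <- function(nonresponse_counts, order = seq_along(nonresponse_counts),
                             exposure = NULL) {
  y <- nonresponse_counts
  if (any(y < 0)) stop("counts must be non-negative")
  if (all(y == 0)) stop("all counts are zero: no trend is estimable")
  df <- data.frame(y = y, ord = as.numeric(order))
  fit <- if (is.null(exposure)) {
    suppressWarnings(MASS::glm.nb(y ~ ord, data = df))
  } else {
    df$off <- log(exposure)
    suppressWarnings(MASS::glm.nb(y ~ ord + offset(off), data = df))
  }
  sm <- summary(fit)$coefficients
  slope <- sm["ord", "Estimate"]
  se <- sm["ord", "Std. Error"]
  z <- slope / se
  list(slope = slope, se = se,
       p_two_sided = 2 * pnorm(-abs(z)),
       p_positive_trend = pnorm(z, lower.tail = FALSE),
       dispersion = fit$theta)
}

#' Simple polygenic score from per-variant weights
#'
#' `score_i = sum_j w_j * dosage_ij`, standardized. Weights are aligned to
#' variants by snp id and effect allele; a mismatch is an error.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights data.frame with `snp`, `a1`, `beta` (or a bare numeric
#'   vector aligned to the variant table).
#' @return standardized per-person score (raw scores in attribute `raw`).
#' @export
simple_prs <- function(genotypes, weights) {
  v <- genotypes$variants
  if (is.numeric(weights)) {
    if (length(weights) != nrow(v)) stop("weight length does not match variants")
    w <- weights
  } else {
    idx <- match(v$snp, weights$snp)
    if (anyNA(idx)) stop("weights missing for variants: ",
                         paste(utils::head(v$snp[is.na(idx)]), collapse = ", "))
    if (!all(weights$a1[idx] == v$a1))
      stop("effect-allele mismatch between weights and variants")
    w <- weights$beta[idx]
  }
  raw <- drop(genotypes$dosage %*% w)
  out <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else raw
  attr(out, "raw") <- raw
  out
}
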