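# GWAS engine: QC filters, covariate-adjusted per-variant linear
# regression (Frisch-Waugh residualization, exact OLS), greedy LD clumping
# and Deming comparison of two sets of summary statistics.

#' Build the standard covariate design
#'
#' Sex, age, age^2, sex x age^2 and the leading genotype principal
#' components, as used for survey-cohort GWAS. Age terms are centered
#' before squaring to limit collinearity. No intercept column (the
#' regression adds its own).
#'
#' @param covariates data.frame with `sex`, `age` and `PC*` columns (e.g.
#'   from [simulate_covariates()]).
#' @param n_pcs number of PCs to keep (default: all present).
#' @return numeric matrix of class `"covariate_design"`, full column rank.
#' @export
covariate_design <- function(covariates, n_pcs = NULL) {
  pcs <- grep("^PC", names(covariates), value = TRUE)
  if (!is.null(n_pcs)) pcs <- pcs[seq_len(min(n_pcs, length(pcs)))]
  age_c <- covariates$age - mean(covariates$age)
  X <- cbind(sex = covariates$sex, age = age_c, age2 = age_c^2,
             sex_age2 = covariates$sex * age_c^2)
  if (length(pcs) > 0) X <- cbind(X, as.matrix(covariates[pcs]))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) stop("covariate design is rank deficient")
  structure(X, class = c("covariate_design", "matrix"))
}

#' Hardy-Weinberg equilibrium chi-square test (1 df)
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return list with `chisq` and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_bb + n_ab) / (2 * n)
  e <- c(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
  o <- c(n_aa, n_ab, n_bb)
  chisq <- sum((o - e)^2 / pmax(e, 1e-300))
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Variant QC filter
#'
#' Removes variants failing minor allele frequency, imputation-quality
#' (INFO) or Hardy-Weinberg filters, plus monomorphic variants. Thresholds
#' default to the common survey-biobank GWAS settings (MAF > 0.01,
#' INFO > 0.8, HWE P > 1e-10).
#'
#' @param genotypes a `genotype_matrix`.
#' @param maf_min,hwe_p_min,info_min thresholds.
#' @return filtered `genotype_matrix`; attribute `removal_log` is a
#'   data.frame (snp, reason) of removed variants.
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, hwe_p_min = 1e-10,
                      info_min = 0.8) {
  G <- genotypes$dosage
  v <- genotypes$variants
  eaf <- colMeans(G) / 2
  maf <- pmin(eaf, 1 - eaf)
  mono <- apply(G, 2, function(x) length(unique(x)) == 1)
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    x <- round(G[, j])
    hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))$p
  }, numeric(1))
  reason <- rep(NA_character_, ncol(G))
  reason[hwe_p <= hwe_p_min] <- "hwe"
  reason[v$info <= info_min] <- "info"
  reason[maf <= maf_min] <- "maf"
  reason[mono] <- "monomorphic"
  keep <- is.na(reason)
  log <- data.frame(snp = v$snp[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  out <- structure(list(dosage = G[, keep, drop = FALSE],
                        variants = v[keep, , drop = FALSE]),
                   class = "genotype_matrix")
  attr(out, "removal_log") <- log
  out
}

#' Covariate-adjusted linear-regression GWAS
#'
#' Per-variant ordinary least squares of the phenotype on dosage plus
#' covariates, computed by residualizing both phenotype and genotype on the
#' covariates (Frisch-Waugh-Lovell), which reproduces the full-design OLS
#' beta, SE and p-value exactly. P-values use the t distribution with the
#' full-design residual degrees of freedom. Individuals with missing
#' phenotype are dropped.
#'
#' @param phenotype numeric vector (NA = missing).
#' @param genotypes a `genotype_matrix`.
#' @param covars a [covariate_design()] (or NULL for intercept-only).
#' @param extra_covars optional additional covariate matrix/vector (e.g. an
#'   inverse Mills ratio column), aligned to the full phenotype vector.
#' @return data.frame of class `"gwas_result"`: snp, chr, pos, a1, a2, eaf,
#'   beta, se, p, n, plus attribute `skipped` for constant residualized
#'   variants.
#' @export
run_gwas <- function(phenotype, genotypes, covars = NULL, extra_covars = NULL) {
  G <- genotypes$dosage
  v <- genotypes$variants
  obs <- which(!is.na(phenotype))
  y <- phenotype[obs]
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covars)) X <- cbind(X, unclass(covars)[obs, , drop = FALSE])
  if (!is.null(extra_covars)) {
    ec <- as.matrix(extra_covars)
    X <- cbind(X, ec[obs, , drop = FALSE])
  }
  p_cov <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p_cov) stop("covariate design is rank deficient")
  Gm <- G[obs, , drop = FALSE]
  ry <- qr.resid(qrX, y)
  rg <- qr.resid(qrX, Gm)
  gss <- colSums(rg^2)
  ok <- gss > 1e-10
  df <- n - p_cov - 1
  beta <- se <- p <- rep(NA_real_, ncol(G))
  gy <- colSums(rg * ry)
  beta[ok] <- gy[ok] / gss[ok]
  rss <- sum(ry^2) - beta[ok]^2 * gss[ok]
  sigma2 <- rss / df
  se[ok] <- sqrt(sigma2 / gss[ok])
  tval <- beta[ok] / se[ok]
  p[ok] <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  res <- data.frame(snp = v$snp, chr = v$chr, pos = v$pos,
                    a1 = v$a1, a2 = v$a2,
                    eaf = colMeans(Gm) / 2,
                    beta = beta, se = se, p = p, n = n,
                    stringsAsFactors = FALSE)
  skipped <- v$snp[!ok]
  res <- res[ok, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gwas_result", "data.frame")
  attr(res, "skipped") <- skipped
  res
}

#' Flag genome-wide significant variants
#' @param result a `gwas_result`.
#' @param threshold significance threshold (default 5e-8).
#' @return logical vector.
#' @export
genome_wide_significant <- function(result, threshold = 5e-8) {
  result$p < threshold
}

#' Pairwise LD r-squared from dosages
#' @param genotypes a `genotype_matrix`.
#' @return m x m matrix of squared dosage correlations.
#' @export
ld_matrix <- function(genotypes) {
  r <- suppressWarnings(cor(genotypes$dosage))
  r[!is.finite(r)] <- 0
  r^2
}

#' Greedy LD clumping into independent loci
#'
#' Repeatedly takes the most significant unassigned variant below
#' `p_thresh` as a lead, assigns as members all unassigned variants within
#' `window` bp with LD `r^2 > r2_member`, and requires leads to be mutually
#' independent at `r^2 < r2_lead`.
#'
#' @param result a `gwas_result`.
#' @param ld LD r-squared matrix aligned to `result` rows.
#' @param p_thresh,r2_lead,r2_member,window clumping thresholds (defaults:
#'   5e-8, 0.1, 0.6, 250000 bp, inclusive, 1-based positions).
#' @return list of loci; each is a list with `lead`, `members` (snp ids,
#'   lead included), `chr`, `start`, `end`.
#' @export
clump_loci <- function(result, ld, p_thresh = 5e-8, r2_lead = 0.1,
                       r2_member = 0.6, window = 250000) {
  stopifnot(nrow(ld) == nrow(result), ncol(ld) == nrow(result))
  assigned <- rep(FALSE, nrow(result))
  leads <- integer(0)
  loci <- list()
  repeat {
    cand <- which(!assigned & result$p < p_thresh)
    # leads must be independent of earlier leads
    if (length(leads) > 0 && length(cand) > 0)
      cand <- cand[apply(ld[cand, leads, drop = FALSE] < r2_lead, 1, all)]
    if (length(cand) == 0) break
    lead <- cand[which.min(result$p[cand])]
    in_window <- result$chr == result$chr[lead] &
      abs(result$pos - result$pos[lead]) <= window
    members <- which(!assigned & in_window & ld[, lead] > r2_member)
    members <- union(lead, members)
    assigned[members] <- TRUE
    leads <- c(leads, lead)
    loci[[length(loci) + 1]] <-
      list(lead = result$snp[lead], members = result$snp[members],
           chr = result$chr[lead],
           start = min(result$pos[members]), end = max(result$pos[members]))
  }
  loci
}

#' Deming (errors-in-variables) comparison of two GWAS
#'
#' Regresses `b2` on `b1` treating both as measured with error; the error
#' variance ratio is `mean(se2^2) / mean(se1^2)`. The standard error of the
#' slope is the leave-one-out jackknife, and the test is two-sided for
#' slope = 1.
#'
#' @param b1,se1,b2,se2 aligned effect/SE vectors (x = `b1`, y = `b2`).
#' @return list with `slope`, `intercept`, `slope_se`, `p_slope_eq_1`,
#'   `n`, `lambda_ratio`.
#' @export
deming_compare <- function(b1, se1, b2, se2) {
  ok <- is.finite(b1) & is.finite(b2) & is.finite(se1) & is.finite(se2)
  b1 <- b1[ok]; b2 <- b2[ok]; se1 <- se1[ok]; se2 <- se2[ok]
  n <- length(b1)
  if (n < 3) stop("need at least 3 points for Deming regression")
  if (any(se1 <= 0) || any(se2 <= 0)) stop("degenerate standard errors")
  lam <- mean(se2^2) / mean(se1^2)
  dem_slope <- function(x, y) {
    sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
    if (abs(sxy) < 1e-300) stop("degenerate variance: covariance is zero")
    (syy - lam * sxx + sqrt((syy - lam * sxx)^2 + 4 * lam * sxy^2)) / (2 * sxy)
  }
  slope <- dem_slope(b1, b2)
  jack <- vapply(seq_len(n), function(i) dem_slope(b1[-i], b2[-i]), numeric(1))
  slope_se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  p_eq_1 <- if (slope_se < 1e-300) {
    if (abs(slope - 1) < 1e-12) 1 else 0
  } else 2 * pnorm(-abs(slope - 1) / slope_se)
  list(slope = slope, intercept = mean(b2) - slope * mean(b1),
       slope_se = slope_se, p_slope_eq_1 = p_eq_1,
       n = n, lambda_ratio = lam)
}
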