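# Synthetic cohort generator.
#
# Emulates a survey biobank with participant-selected item nonresponse:
# genotypes with block LD, latent "Prefer not to answer" (PNA, code -3) and
# "I don't know" (IDK, code -1) nonresponse factors with a genetic
# component, item indicators from a bifactor liability model, a quantitative
# target phenotype, and MNAR missingness from a probit selection model
# (phenotype -> selection theta, mediator -> selection gamma, nonresponse
# factor -> selection). Full ground truth is retained so every downstream
# stage can be checked by parameter recovery.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic cohort. Defaults
#' define the reference study conditions; path strengths in the selection
#' model are presets chosen for demonstrability, not estimates.
#'
#' @param n_individuals,n_variants cohort and panel size.
#' @param maf_range allele-frequency range, within (0, 1).
#' @param ld_block_size variants per LD block.
#' @param ld_rho latent (Gaussian-copula) within-block correlation in [0, 1).
#' @param n_items,n_domains survey items and domain-specific factors.
#' @param general_loading,domain_loading bifactor liability loadings in (0, 1);
#'   squared sum must stay below 1. `general_loading` may be a length-2
#'   range, in which case item loadings are spaced across it.
#' @param item_threshold_range probit thresholds for PNA indicators (higher =
#'   rarer nonresponse); IDK thresholds are these minus `idk_threshold_shift`,
#'   making IDK the commoner response as observed in survey data.
#' @param idk_threshold_shift see above.
#' @param prop_items_idk fraction of items that offer the IDK option.
#' @param alpha_snp_phenotype per-variant effect scale of SNPs on the
#'   phenotype (dosage scale), at the causal variants.
#' @param beta_snp_nonresponse effect scale of SNPs on the nonresponse factor
#'   liability; 0 switches the genetic path off.
#' @param alpha_beta_cor correlation between SNP effects on the phenotype and
#'   on the nonresponse factor at causal variants (genetic overlap of the
#'   target trait with nonresponse; negative mirrors e.g. cognition).
#' @param n_causal number of causal variants for the phenotype.
#' @param n_causal_nonresponse number of variants with nonzero effect on
#'   the nonresponse factor; 0 (default) means fully polygenic (every
#'   variant contributes). Positive values concentrate the factor's genetic
#'   architecture on the same evenly spaced variant grid used for the
#'   phenotype's causal set.
#' @param h2_factor,h2_phenotype SNP-heritabilities in [0, 1).
#' @param factor_cor latent correlation between the PNA and IDK general
#'   factors (default 0.73, the preset taken from observed data).
#' @param theta_pheno_selection,gamma_mediator_selection,selection_factor_weight
#'   probit selection paths: phenotype, mediator, and PNA general factor.
#' @param eta_mediator_phenotype mediator effect on the phenotype.
#' @param delta_snp_mediator SNP-heritability of the mediator in [0, 1).
#' @param target_missing_frac marginal missingness rate; the selection
#'   intercept is calibrated to it by bisection.
#' @param followup_intercept,followup_coef_pna,followup_coef_idk probit
#'   parameters of follow-up participation (positive coefficients lower
#'   participation for high-nonresponse individuals). Defaults are
#'   calibrated so the two factors jointly add an incremental Cox-Snell
#'   pseudo-R2 of about 0.056 for predicting follow-up nonresponse, the
#'   reference scenario for the prediction stage.
#' @param n_pcs genotype principal components kept as covariates.
#' @param seed integer RNG seed (< 2^31 - 100).
#' @return object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_individuals = 2000, n_variants = 200,
                       maf_range = c(0.05, 0.45), ld_block_size = 10,
                       ld_rho = 0.3,
                       n_items = 40, n_domains = 4,
                       general_loading = 0.6, domain_loading = 0.5,
                       item_threshold_range = c(1.2, 2.2),
                       idk_threshold_shift = 1.0, prop_items_idk = 0.76,
                       alpha_snp_phenotype = 0.15,
                       beta_snp_nonresponse = 1,
                       alpha_beta_cor = 0, n_causal = 20,
                       n_causal_nonresponse = 0,
                       h2_factor = 0.2, h2_phenotype = 0.3,
                       factor_cor = 0.73,
                       theta_pheno_selection = 0,
                       gamma_mediator_selection = 0,
                       selection_factor_weight = 0,
                       eta_mediator_phenotype = 0,
                       delta_snp_mediator = 0.2,
                       target_missing_frac = 0.3,
                       followup_intercept = 0.5,
                       followup_coef_pna = 0.16, followup_coef_idk = 0.19,
                       n_pcs = 4, seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = as.numeric(ld_rho),
              n_items = as.integer(n_items), n_domains = as.integer(n_domains),
              general_loading = general_loading,
              domain_loading = domain_loading,
              item_threshold_range = as.numeric(item_threshold_range),
              idk_threshold_shift = idk_threshold_shift,
              prop_items_idk = prop_items_idk,
              alpha_snp_phenotype = alpha_snp_phenotype,
              beta_snp_nonresponse = beta_snp_nonresponse,
              alpha_beta_cor = alpha_beta_cor, n_causal = as.integer(n_causal),
              n_causal_nonresponse = as.integer(n_causal_nonresponse),
              h2_factor = h2_factor, h2_phenotype = h2_phenotype,
              factor_cor = factor_cor,
              theta_pheno_selection = theta_pheno_selection,
              gamma_mediator_selection = gamma_mediator_selection,
              selection_factor_weight = selection_factor_weight,
              eta_mediator_phenotype = eta_mediator_phenotype,
              delta_snp_mediator = delta_snp_mediator,
              target_missing_frac = target_missing_frac,
              followup_intercept = followup_intercept,
              followup_coef_pna = followup_coef_pna,
              followup_coef_idk = followup_coef_idk,
              n_pcs = as.integer(n_pcs), seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals > 0, cfg$n_variants > 0, cfg$n_items > 0,
            cfg$n_domains > 0, cfg$ld_block_size > 0, cfg$n_causal >= 0)
  if (cfg$n_causal > cfg$n_variants)
    stop("n_causal cannot exceed n_variants")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range >= 1) ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an ordered pair within (0, 1)")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  for (f in c("h2_factor", "h2_phenotype", "delta_snp_mediator")) {
    v <- cfg[[f]]
    if (v < 0 || v >= 1) stop(f, " must be a variance fraction in [0, 1)")
  }
  if (abs(cfg$factor_cor) > 1 || abs(cfg$alpha_beta_cor) > 1)
    stop("correlations must lie in [-1, 1]")
  if (max(cfg$general_loading)^2 + cfg$domain_loading^2 >= 1)
    stop("general_loading^2 + domain_loading^2 must be < 1")
  if (cfg$target_missing_frac <= 0 || cfg$target_missing_frac >= 1)
    stop("target_missing_frac must be in (0, 1)")
  if (abs(cfg$seed) > 2^31 - 100) stop("seed out of integer range")
  invisible(cfg)
}

#' Simulate genotype dosages with block LD
#'
#' Haplotypes come from a Gaussian copula: within a block the latent normals
#' share correlation `ld_rho` (exchangeable), across blocks they are
#' independent; thresholding at the allele frequency yields alleles, and two
#' haplotypes sum to a dosage in {0, 1, 2}. Realized dosage correlation is
#' slightly below `ld_rho` (threshold attenuation).
#'
#' @param config a [sim_config()].
#' @return object of class `"genotype_matrix"`: list with `dosage` (n x m
#'   integer matrix) and `variants` (data.frame: snp, chr, pos, a1, a2, maf,
#'   info; 1-based positions).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_individuals; m <- config$n_variants
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  block <- ((seq_len(m) - 1L) %/% config$ld_block_size) + 1L
  nb <- max(block)
  thr <- qnorm(p)
  dosage <- matrix(0L, n, m)
  r <- config$ld_rho
  for (hap in 1:2) {
    common <- matrix(rnorm(n * nb), n, nb)
    z <- sqrt(r) * common[, block, drop = FALSE] +
      sqrt(1 - r) * matrix(rnorm(n * m), n, m)
    dosage <- dosage + (z < rep(thr, each = n))
  }
  storage.mode(dosage) <- "integer"
  variants <- data.frame(
    snp = sprintf("snp%04d", seq_len(m)),
    chr = 1L,
    pos = 1L + (seq_len(m) - 1L) * 5000L,
    a1 = "A", a2 = "G",
    maf = p,
    info = runif(m, 0.81, 1),
    block = block,
    stringsAsFactors = FALSE)
  colnames(dosage) <- variants$snp
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (mean MAF %.3f)\n",
              nrow(x$dosage), ncol(x$dosage), mean(x$variants$maf)))
  invisible(x)
}

# column-standardize dosages (constant columns -> 0)
.std_geno <- function(G) {
  s <- apply(G, 2, sd)
  s[s == 0] <- Inf
  scale(G, center = TRUE, scale = s)
}

#' Simulate latent nonresponse factors
#'
#' Builds correlated PNA-like and IDK-like general nonresponse factors with
#' SNP-heritability `h2_factor` (genetic score = standardized weighted dosage
#' sum, weights N(0, beta^2)), plus independent standard-normal domain
#' factors for each response type. The IDK factor is a `factor_cor`-weighted
#' blend of the PNA factor and an independently built factor, so the
#' realized latent correlation tracks the configured preset.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param config a [sim_config()].
#' @return object of class `"cohort_truth"`: list with `general` (list
#'   `pna`, `idk` of N-vectors), `domains` (list of N x k matrices),
#'   `snp_effects_nonresponse` (m-vector, PNA liability weights).
#' @export
simulate_nonresponse_factors <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- config$n_individuals; m <- config$n_variants
  Gs <- .std_geno(genotypes$dosage)
  h2 <- config$h2_factor
  bscale <- config$beta_snp_nonresponse
  mk_factor <- function(b) {
    if (bscale > 0 && h2 > 0) {
      g <- as.vector(Gs %*% b)
      g <- (g - mean(g)) / sd(g)
      sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)
    } else rnorm(n)
  }
  b1 <- rnorm(m, 0, max(bscale, 1e-12))
  b2 <- rnorm(m, 0, max(bscale, 1e-12))
  if (config$n_causal_nonresponse > 0) {
    mask <- rep(0, m)
    mask[round(seq(1, m, length.out = config$n_causal_nonresponse))] <- 1
    b1 <- b1 * mask
    b2 <- b2 * mask
  }
  f_pna <- mk_factor(b1)
  f_ind <- mk_factor(b2)
  fc <- config$factor_cor
  f_idk <- fc * f_pna + sqrt(1 - fc^2) * f_ind
  f_pna <- (f_pna - mean(f_pna)) / sd(f_pna)
  f_idk <- (f_idk - mean(f_idk)) / sd(f_idk)
  k <- config$n_domains
  structure(list(
    general = list(pna = f_pna, idk = f_idk),
    domains = list(pna = matrix(rnorm(n * k), n, k),
                   idk = matrix(rnorm(n * k), n, k)),
    snp_effects_nonresponse = if (bscale > 0) b1 else numeric(m)),
    class = "cohort_truth")
}

#' Item domain assignment used by the simulator (round-robin)
#' @param n_items,n_domains counts.
#' @return integer vector of domain ids per item.
#' @export
item_domains <- function(n_items, n_domains) {
  sort(rep_len(seq_len(n_domains), n_items))
}

#' Simulate coded item responses
#'
#' Each item's nonresponse indicator fires when its bifactor liability
#' (general loading on the shared factor, domain loading on its domain
#' factor, unique normal noise) exceeds the item threshold. PNA takes
#' precedence: a cell is coded -3 (PNA), else -1 (IDK, where the item offers
#' it), else a substantive answer in 0..4. PNA and IDK are therefore
#' mutually exclusive per cell by construction.
#'
#' @param truth a [simulate_nonresponse_factors()] result.
#' @param config a [sim_config()].
#' @return integer matrix (class `"item_matrix"`) with attributes
#'   `idk_allowed` (logical per item), `domain` (int per item) and
#'   `degenerate` (list of flagged all-0/all-1 indicator items).
#' @export
simulate_item_responses <- function(truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  n <- config$n_individuals; q <- config$n_items
  lg <- config$general_loading
  lg <- if (length(lg) == 2) seq(lg[1], lg[2], length.out = q) else rep(lg, q)
  ld <- config$domain_loading
  uniq <- sqrt(1 - lg^2 - ld^2)
  dom <- item_domains(q, config$n_domains)
  tau_pna <- seq(config$item_threshold_range[1], config$item_threshold_range[2],
                 length.out = q)
  tau_idk <- tau_pna - config$idk_threshold_shift
  idk_allowed <- seq_len(q) <= round(config$prop_items_idk * q)

  liab <- function(f_gen, doms)
    outer(f_gen, lg) + ld * doms[, dom, drop = FALSE] +
      matrix(rnorm(n * q), n, q) %*% diag(uniq)
  pna_ind <- sweep(liab(truth$general$pna, truth$domains$pna), 2, tau_pna, ">")
  idk_ind <- sweep(liab(truth$general$idk, truth$domains$idk), 2, tau_idk, ">")
  idk_ind <- idk_ind & rep(idk_allowed, each = n)

  X <- matrix(sample(0:4, n * q, replace = TRUE), n, q)
  X[idk_ind] <- -1L
  X[pna_ind] <- -3L           # PNA precedence: one nonresponse code per cell
  storage.mode(X) <- "integer"
  colnames(X) <- sprintf("item%02d", seq_len(q))

  degen <- list(pna = colnames(X)[colMeans(X == -3) %in% c(0, 1)],
                idk = colnames(X)[idk_allowed & colMeans(X == -1) %in% c(0, 1)])
  if (length(degen$pna) == q || length(degen$idk) == sum(idk_allowed))
    warning("thresholds produced degenerate indicators for every item")
  structure(X, class = c("item_matrix", class(X)),
            idk_allowed = idk_allowed, domain = dom, degenerate = degen,
            loading_general = lg, loading_domain = rep(ld, q),
            threshold_pna = tau_pna, threshold_idk = tau_idk)
}

#' Simulate the target phenotype, mediator and MNAR missingness
#'
#' The phenotype is `Y = sum_j alpha_j g_ij + eta * Z + e`, with `alpha`
#' drawn at `n_causal` variants (correlated `alpha_beta_cor` with the
#' nonresponse-factor SNP effects at those variants) and noise scaled so the
#' causal SNPs explain `h2_phenotype` of the non-mediated variance. The
#' mediator `Z` has SNP-heritability `delta_snp_mediator`. Missingness
#' follows `P(miss) = Phi(b0 + theta*Y_std + gamma*Z + w*I_pna)` with `b0`
#' calibrated by bisection to `target_missing_frac`.
#'
#' @param genotypes,truth,config simulator objects.
#' @return list with `phenotype`, `mediator`, `missing` (logical: TRUE =
#'   phenotype unobserved), `observed` (= !missing), `true_beta` (m-vector of
#'   marginal dosage-scale effects implied by the generative model),
#'   `causal_idx`, `alpha`, `selection` (list: intercept, linear predictor,
#'   implied missing rate).
#' @export
simulate_target_phenotype <- function(genotypes, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  G <- genotypes$dosage
  n <- nrow(G); m <- ncol(G)
  Gc <- scale(G, center = TRUE, scale = FALSE)

  # mediator Z (Fig.-1 style G -> Z -> {Y, S})
  d <- config$delta_snp_mediator
  if (d > 0) {
    bz <- rnorm(m)
    gz <- as.vector(.std_geno(G) %*% bz)
    Z <- sqrt(d) * (gz - mean(gz)) / sd(gz) + sqrt(1 - d) * rnorm(n)
  } else Z <- rnorm(n)
  Z <- (Z - mean(Z)) / sd(Z)

  # causal SNP effects on Y, correlated with nonresponse-factor effects
  nc <- config$n_causal
  causal <- if (nc > 0) round(seq(1, m, length.out = nc)) else integer(0)
  alpha <- numeric(m)
  if (nc > 0 && config$alpha_snp_phenotype > 0) {
    b <- truth$snp_effects_nonresponse[causal]
    b_std <- if (sd(b) > 0) (b - mean(b)) / sd(b) else rnorm(nc)
    r <- config$alpha_beta_cor
    alpha[causal] <- config$alpha_snp_phenotype *
      (r * b_std + sqrt(1 - r^2) * rnorm(nc))
  }
  C <- as.vector(Gc %*% alpha)
  h2 <- config$h2_phenotype
  sig_e <- if (var(C) > 0 && h2 > 0) sqrt(var(C) * (1 - h2) / h2) else 1
  Y <- C + config$eta_mediator_phenotype * Z + rnorm(n, 0, sig_e)

  # generative marginal (full-data) effect of each variant on E[Y]
  EY <- C + config$eta_mediator_phenotype * Z
  vg <- apply(Gc, 2, function(x) sum(x^2))
  true_beta <- as.vector(crossprod(Gc, EY - mean(EY))) / pmax(vg, 1e-12)

  # probit selection, intercept calibrated by bisection
  lp_raw <- config$theta_pheno_selection * (Y - mean(Y)) / sd(Y) +
    config$gamma_mediator_selection * Z +
    config$selection_factor_weight * truth$general$pna
  b0 <- uniroot(function(b) mean(pnorm(b + lp_raw)) - config$target_missing_frac,
                c(-15, 15), tol = 1e-10)$root
  p_miss <- pnorm(b0 + lp_raw)
  missing <- runif(n) < p_miss

  list(phenotype = Y, mediator = Z, missing = missing, observed = !missing,
       true_beta = true_beta, causal_idx = causal, alpha = alpha,
       selection = list(intercept = b0, linear_predictor = b0 + lp_raw,
                        implied_missing_rate = mean(p_miss)))
}

#' Simulate follow-up participation
#'
#' Probit participation model on the general nonresponse factors:
#' `P(participate) = Phi(intercept - c_pna * I_pna - c_idk * I_idk)`, so
#' positive coefficients make high-nonresponse individuals less likely to
#' take part in the follow-up.
#'
#' @param truth a `cohort_truth`.
#' @param config a [sim_config()].
#' @return list with `participation` (0/1 vector) and `linear_predictor`.
#' @export
simulate_followup_participation <- function(truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 5L)
  lp <- config$followup_intercept -
    config$followup_coef_pna * truth$general$pna -
    config$followup_coef_idk * truth$general$idk
  part <- as.integer(runif(config$n_individuals) < pnorm(lp))
  list(participation = part, linear_predictor = lp)
}

#' Simulate basic covariates (sex, age) and genotype principal components
#' @param genotypes genotype matrix.
#' @param config a [sim_config()].
#' @return data.frame with `sex` (0/1), `age`, and `PC1..PCk`.
#' @export
simulate_covariates <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 6L)
  n <- config$n_individuals
  sex <- rbinom(n, 1, 0.54)
  age <- sample(40:69, n, replace = TRUE)
  k <- min(config$n_pcs, ncol(genotypes$dosage), n - 1)
  pcs <- prcomp(.std_geno(genotypes$dosage), center = FALSE,
                scale. = FALSE, rank. = k)$x
  out <- data.frame(sex = sex, age = age)
  out[paste0("PC", seq_len(k))] <- pcs[, seq_len(k), drop = FALSE]
  out
}

#' Run the whole simulator
#'
#' Convenience wrapper composing all `simulate_*` operations with one seed.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genotypes`, `truth`, `items`, `pheno`
#'   (the [simulate_target_phenotype()] result), `followup`, `covariates`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  truth <- simulate_nonresponse_factors(geno, config)
  items <- simulate_item_responses(truth, config)
  pheno <- simulate_target_phenotype(geno, truth, config)
  followup <- simulate_followup_participation(truth, config)
  covars <- simulate_covariates(geno, config)
  list(config = config, genotypes = geno, truth = truth, items = items,
       pheno = pheno, followup = followup, covariates = covars)
}
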