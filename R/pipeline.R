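# End-to-end orchestration: simulate -> construct factors -> GWAS ->
# Heckman -> follow-up prediction, with a manifest and structured log.

#' Pipeline configuration
#'
#' Bundles the simulator configuration with the analysis parameters.
#' Unknown names in `...` are rejected.
#'
#' @param sim a [sim_config()].
#' @param ... overrides for the analysis defaults: `cut_height_pna`
#'   (0.500), `cut_height_idk` (0.775), `n_group_factors_pna` (5),
#'   `n_group_factors_idk` (4), `efa_fraction` (0.8), `maf_min` (0.01),
#'   `hwe_p_min` (1e-10), `info_min` (0.8), `p_thresh` (5e-8), `r2_lead`
#'   (0.1), `r2_member` (0.6), `clump_window` (250000), `n_pcs_covars`
#'   (4), `stages` (character subset of simulate/factors/gwas/heckman/
#'   predict).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  cfg <- list(sim = sim,
              cut_height_pna = 0.500, cut_height_idk = 0.775,
              n_group_factors_pna = 5L, n_group_factors_idk = 4L,
              efa_fraction = 0.8,
              maf_min = 0.01, hwe_p_min = 1e-10, info_min = 0.8,
              p_thresh = 5e-8, r2_lead = 0.1, r2_member = 0.6,
              clump_window = 250000,
              n_pcs_covars = 4L,
              stages = c("simulate", "factors", "gwas", "heckman", "predict"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown pipeline configuration keys: ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(log_path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", file = log_path, sep = "", append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages into `out_dir`, writing each artifact as
#' TSV plus a manifest (file, md5 checksum) and a run log. Stage failures
#' abort with the stage name; artifacts of completed stages remain.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest` path.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  .log_stage(log_path, paste("seed:", config$sim$seed))
  write_sim_config(config$sim, file.path(out_dir, "sim_config.txt"))
  res <- list(config = config)
  stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(NULL)
    .log_stage(log_path, paste("stage", name, "start"))
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .log_stage(log_path, paste("stage", name, "done"))
    out
  }

  res$cohort <- stage("simulate", {
    co <- simulate_cohort(config$sim)
    write_item_matrix(co$items, file.path(out_dir, "items.tsv"))
    write_genotypes(co$genotypes, file.path(out_dir, "geno"))
    ph <- data.frame(phenotype = co$pheno$phenotype,
                     missing = as.integer(co$pheno$missing),
                     mediator = co$pheno$mediator,
                     followup = co$followup$participation,
                     co$covariates)
    .write_tsv(ph, file.path(out_dir, "phenotypes.tsv"))
    .write_tsv(data.frame(snp = co$genotypes$variants$snp,
                          alpha = co$pheno$alpha,
                          beta_nonresponse = co$truth$snp_effects_nonresponse,
                          true_marginal_beta = co$pheno$true_beta),
               file.path(out_dir, "truth_snp_effects.tsv"))
    .write_tsv(data.frame(general_pna = co$truth$general$pna,
                          general_idk = co$truth$general$idk),
               file.path(out_dir, "truth_factors.tsv"))
    co
  })
  co <- res$cohort

  res$factors <- stage("factors", {
    fp <- construct_nonresponse_factors(
      co$items, "pna", cut_height = config$cut_height_pna,
      n_group_factors = config$n_group_factors_pna,
      efa_fraction = config$efa_fraction, seed = config$sim$seed)
    fi <- construct_nonresponse_factors(
      co$items, "idk", cut_height = config$cut_height_idk,
      n_group_factors = config$n_group_factors_idk,
      efa_fraction = config$efa_fraction, seed = config$sim$seed)
    .write_tsv(data.frame(score_pna = fp$scores$general,
                          score_idk = fi$scores$general),
               file.path(out_dir, "factor_scores.tsv"))
    for (nm in c("pna", "idk")) {
      m <- if (nm == "pna") fp$model else fi$model
      .write_tsv(data.frame(indicator = names(m$general_loadings),
                            general = m$general_loadings,
                            m$group_loadings),
                 file.path(out_dir, paste0("loadings_", nm, ".tsv")))
      .write_tsv(data.frame(index = c("rmsea", "tli", "srmr"),
                            value = c(m$fit$rmsea, m$fit$tli, m$fit$srmr)),
                 file.path(out_dir, paste0("fit_", nm, ".tsv")))
    }
    list(pna = fp, idk = fi)
  })

  res$gwas <- stage("gwas", {
    qc <- qc_filter(co$genotypes, maf_min = config$maf_min,
                    hwe_p_min = config$hwe_p_min, info_min = config$info_min)
    cd <- covariate_design(co$covariates, n_pcs = config$n_pcs_covars)
    score <- if (!is.null(res$factors)) res$factors$pna$scores$general
             else co$truth$general$pna
    gw <- run_gwas(score, qc, cd)
    write_sumstats(gw, file.path(out_dir, "gwas_factor_pna.tsv"))
    loci <- clump_loci(gw, ld_matrix(qc), p_thresh = config$p_thresh,
                       r2_lead = config$r2_lead,
                       r2_member = config$r2_member,
                       window = config$clump_window)
    write_loci(loci, file.path(out_dir, "loci_factor_pna.tsv"))
    list(qc = qc, covars = cd, result = gw, loci = loci)
  })

  res$heckman <- stage("heckman", {
    qc <- res$gwas$qc %||% qc_filter(co$genotypes)
    cd <- res$gwas$covars %||% covariate_design(co$covariates,
                                                n_pcs = config$n_pcs_covars)
    yobs <- co$pheno$phenotype
    yobs[co$pheno$missing] <- NA
    score_pna <- if (!is.null(res$factors)) res$factors$pna$scores$general
                 else co$truth$general$pna
    score_idk <- if (!is.null(res$factors)) res$factors$idk$scores$general
                 else co$truth$general$idk
    Zsel <- cbind(score_pna = score_pna, score_idk = score_idk,
                  mediator = co$pheno$mediator, unclass(cd))
    hk <- heckman_gwas(yobs, qc, cd, Zsel,
                       response_extra = cbind(mediator = co$pheno$mediator))
    write_sumstats(hk$uncorrected, file.path(out_dir, "gwas_pheno_uncorrected.tsv"))
    write_sumstats(hk$corrected, file.path(out_dir, "gwas_pheno_heckman.tsv"))
    .write_tsv(data.frame(term = c("lambda_coef", "lambda_se", "lambda_p",
                                   "selection_pseudo_r2"),
                          value = c(hk$lambda_coef, hk$lambda_se, hk$lambda_p,
                                    hk$selection$pseudo_r2)),
               file.path(out_dir, "heckman_summary.tsv"))
    hk
  })

  res$predict <- stage("predict", {
    part <- co$followup$participation
    scores <- if (!is.null(res$factors))
      cbind(score_pna = res$factors$pna$scores$general,
            score_idk = res$factors$idk$scores$general)
    else cbind(score_pna = co$truth$general$pna,
               score_idk = co$truth$general$idk)
    base <- as.matrix(co$covariates[c("sex", "age")])
    inc <- incremental_pseudo_r2(1 - part, base, cbind(base, scores))
    fit <- logistic_fit(1 - part, cbind(base, scores))
    z <- fit$coefficients / fit$se
    .write_tsv(data.frame(term = names(fit$coefficients),
                          estimate = fit$coefficients, se = fit$se,
                          p = 2 * pnorm(-abs(z))),
               file.path(out_dir, "followup_model.tsv"))
    .write_tsv(data.frame(method = "incremental_cox_snell", value = inc),
               file.path(out_dir, "followup_metrics.tsv"))
    list(fit = fit, incremental_r2 = inc)
  })

  files <- setdiff(list.files(out_dir), c("manifest.tsv", "run.log"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         seed = config$sim$seed)
  .write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  .log_stage(log_path, "pipeline complete")
  res$manifest <- file.path(out_dir, "manifest.tsv")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
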