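# Tab-delimited I/O for the pipeline's tables: item responses, genotypes,
# summary statistics, scores and configs. Floats are written at 6
# significant digits; integer codes round-trip exactly.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write a coded item-response matrix
#'
#' TSV with a header of item identifiers. Valid cell codes are -3 ("Prefer
#' not to answer"), -1 ("I don't know") and non-negative substantive
#' answers; anything else is an error naming the offending row and column.
#' On read, per-item availability of the IDK option is recorded (an item
#' never showing -1 may simply not offer it).
#'
#' @param path file path.
#' @return integer matrix with attribute `idk_allowed`.
#' @export
read_item_matrix <- function(path) {
  df <- .read_tsv(path)
  X <- as.matrix(df)
  storage.mode(X) <- "integer"
  bad <- which(!(X %in% c(-3L, -1L) | X >= 0L), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown response code %d at row %d, column '%s'",
                 X[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(X)[bad[1, 2]]))
  structure(X, idk_allowed = colSums(X == -1L, na.rm = TRUE) > 0)
}

#' @rdname read_item_matrix
#' @param items item matrix to write.
#' @export
write_item_matrix <- function(items, path) {
  X <- as.matrix(items)
  df <- as.data.frame(X)
  if (is.null(colnames(X))) names(df) <- paste0("item", seq_len(ncol(X)))
  .write_tsv(df, path)
}

#' Write / read genotypes (dosage TSV + variant metadata TSV)
#'
#' @param genotypes a `genotype_matrix`.
#' @param prefix output prefix; writes `<prefix>_dosage.tsv` and
#'   `<prefix>_variants.tsv` (chrom/pos/alleles/MAF/INFO, 1-based
#'   positions).
#' @export
write_genotypes <- function(genotypes, prefix) {
  .write_tsv(as.data.frame(genotypes$dosage), paste0(prefix, "_dosage.tsv"))
  .write_tsv(genotypes$variants, paste0(prefix, "_variants.tsv"))
  invisible(prefix)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(prefix) {
  dos <- as.matrix(.read_tsv(paste0(prefix, "_dosage.tsv")))
  v <- .read_tsv(paste0(prefix, "_variants.tsv"))
  structure(list(dosage = dos, variants = v), class = "genotype_matrix")
}

#' Write / read GWAS summary statistics
#'
#' Standard tab-delimited sumstats: SNP, CHR, POS, A1, A2, EAF, BETA, SE,
#' P, N; missing values written as ".".
#'
#' @param result a `gwas_result`.
#' @param path file path.
#' @export
write_sumstats <- function(result, path) {
  df <- data.frame(SNP = result$snp, CHR = result$chr, POS = result$pos,
                   A1 = result$a1, A2 = result$a2, EAF = result$eaf,
                   BETA = result$beta, SE = result$se, P = result$p,
                   N = result$n)
  .write_tsv(df, path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- .read_tsv(path)
  res <- data.frame(snp = df$SNP, chr = df$CHR, pos = df$POS, a1 = df$A1,
                    a2 = df$A2, eaf = df$EAF, beta = df$BETA, se = df$SE,
                    p = df$P, n = df$N, stringsAsFactors = FALSE)
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Write clumped loci as TSV (lead + members)
#' @param loci [clump_loci()] output.
#' @param path file path.
#' @export
write_loci <- function(loci, path) {
  df <- do.call(rbind, lapply(loci, function(l)
    data.frame(lead = l$lead, chr = l$chr, start = l$start, end = l$end,
               n_members = length(l$members),
               members = paste(l$members, collapse = ","))))
  if (is.null(df)) df <- data.frame(lead = character(), chr = integer(),
                                    start = integer(), end = integer(),
                                    n_members = integer(), members = character())
  .write_tsv(df, path)
}

#' Write / read a simulation configuration as key = value text
#'
#' One `key = value` line per field; vector values are comma-separated.
#' Unknown keys on read are rejected.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  keys <- trimws(keys)
  defaults <- formals(sim_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  vals <- lapply(kv, function(x) as.numeric(strsplit(x[2], ",")[[1]]))
  names(vals) <- keys
  do.call(sim_config, vals)
}
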