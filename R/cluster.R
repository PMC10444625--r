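# Residual clustering and branch collapsing.
#
# Items whose nonresponse co-occurs beyond the single general factor are
# grouped by agglomerative clustering of the single-factor EFA residuals
# and collapsed to one indicator per branch, flattening nested structure
# before the bifactor fit.

#' Cluster single-factor EFA residuals into branches
#'
#' Agglomerative (complete-linkage) clustering on the distance
#' `d = 1 - |residual correlation|`; branches are the dendrogram cut at
#' `cut_height`. Reference cut heights of 0.500 (PNA) and 0.775 (IDK) are
#' on this correlation-distance scale.
#'
#' @param residuals symmetric residual matrix (diagonal ignored).
#' @param cut_height dendrogram cut height in [0, 1].
#' @return object of class `"branch_assignment"`: list with `mapping`
#'   (named integer vector item -> branch id), `cut_height`,
#'   `linkage = "complete"` and the `hclust` tree.
#' @export
cluster_residuals <- function(residuals, cut_height) {
  R <- as.matrix(residuals)
  if (!isSymmetric(unname(R), tol = 1e-8)) stop("residual matrix must be symmetric")
  if (is.null(rownames(R))) rownames(R) <- colnames(R) <- paste0("item", seq_len(ncol(R)))
  d <- 1 - abs(R)
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "complete")
  mapping <- cutree(hc, h = cut_height)
  nb <- length(unique(mapping))
  if (nb == 1)
    warning("cut height above all merges: a single branch")
  if (nb == ncol(R) && ncol(R) > 1 && cut_height < min(hc$height))
    warning("cut height below all merges: every item is a singleton branch")
  structure(list(mapping = mapping, cut_height = cut_height,
                 linkage = "complete", tree = hc),
            class = "branch_assignment")
}

#' @export
print.branch_assignment <- function(x, ...) {
  cat(sprintf("branch assignment: %d items -> %d branches (complete linkage, cut %.3f)\n",
              length(x$mapping), length(unique(x$mapping)), x$cut_height))
  invisible(x)
}

#' Collapse item indicators within branches
#'
#' Reduces the per-item nonresponse indicators to one indicator per branch.
#' `mode = "sum"` (IDK convention) counts nonresponses inside the branch.
#' `mode = "ordinal"` (PNA convention) scores 0 = no nonresponse in the
#' branch, 1 = exactly one, 3 = nonresponse to every branch item, 2 =
#' anything else, limiting the influence of all-PNA responders. Singleton
#' branches pass through as the binary indicator.
#'
#' @param items coded item matrix (or 0/1 indicator matrix with
#'   `response_code = "binary"`).
#' @param branches a [cluster_residuals()] result (or named integer vector).
#' @param mode `"sum"` or `"ordinal"`.
#' @param response_code `"pna"`, `"idk"` or `"binary"`.
#' @return integer matrix, one column per branch (named `br<ID>`), with
#'   attribute `branch_items` listing member items.
#' @export
collapse_branches <- function(items, branches, mode = c("sum", "ordinal"),
                              response_code = c("pna", "idk", "binary")) {
  mode <- match.arg(mode)
  response_code <- match.arg(response_code)
  map <- if (inherits(branches, "branch_assignment")) branches$mapping else branches
  if (length(map) == 0) stop("empty branch assignment")
  X <- as.matrix(items)
  ind <- switch(response_code,
                pna = (X == -3) * 1L,
                idk = (X == -1) * 1L,
                binary = X * 1L)
  if (is.null(colnames(ind))) colnames(ind) <- paste0("item", seq_len(ncol(ind)))
  use <- intersect(names(map), colnames(ind))
  if (length(use) == 0 && is.null(names(map))) {
    names(map) <- colnames(ind)[seq_along(map)]
    use <- names(map)
  }
  ids <- sort(unique(map))
  out <- matrix(0L, nrow(ind), length(ids),
                dimnames = list(NULL, paste0("br", ids)))
  members <- vector("list", length(ids))
  names(members) <- colnames(out)
  for (j in seq_along(ids)) {
    its <- names(map)[map == ids[j]]
    if (length(its) == 0) stop("empty branch: ", ids[j])
    members[[j]] <- its
    B <- ind[, its, drop = FALSE]
    s <- rowSums(B)
    out[, j] <- if (length(its) == 1) {
      as.integer(s)
    } else if (mode == "sum") {
      as.integer(s)
    } else {
      as.integer(ifelse(s == 0, 0L,
                 ifelse(s == 1, 1L,
                 ifelse(s == length(its), 3L, 2L))))
    }
  }
  attr(out, "branch_items") <- members
  out
}

#' Reproducible train/holdout split
#'
#' @param n number of individuals.
#' @param fraction first-part fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with disjoint, exhaustive index vectors `first` and `second`.
#' @export
split_sample <- function(n, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  first <- sort(sample.int(n, round(fraction * n)))
  list(first = first, second = setdiff(seq_len(n), first))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
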