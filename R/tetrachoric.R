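# Tetrachoric and polychoric correlation estimation.
#
# Two-step maximum likelihood: thresholds are fixed at the inverse-normal
# transforms of the marginal proportions, then the latent correlation is
# profiled out by 1-D maximization of the multinomial likelihood over
# bivariate-normal rectangle probabilities.

.RHO_EPS <- 1e-6

#' Tetrachoric correlation from a 2x2 table
#'
#' Estimates the correlation of the latent bivariate normal assumed to
#' underlie two dichotomized variables. Thresholds come from the marginal
#' proportions (after a 0.5 continuity correction applied to zero cells);
#' the correlation maximizes the rectangle-probability likelihood.
#'
#' @param table 2x2 matrix of counts; `table[i, j]` is the count of
#'   `x = i - 1`, `y = j - 1` (rows: x = 0/1, columns: y = 0/1).
#' @return object of class `"tetra_estimate"`: a list with `rho`,
#'   thresholds `tau_x`, `tau_y`, `loglik` and a `converged` flag.
#' @details A table whose off-diagonal (or diagonal) cells are both zero is
#'   perfectly concordant (discordant) on the latent scale; the estimate is
#'   clipped to `+/-(1 - 1e-6)` and flagged. Zero margins that survive the
#'   continuity correction are an error: the threshold is not identified.
#' @examples
#' tetrachoric_rho(matrix(c(25, 25, 25, 25), 2))$rho  # 0
#' @export
tetrachoric_rho <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(!is.finite(tab)))
    stop("'table' must be a 2x2 matrix of non-negative counts")
  if (sum(tab) < 10) stop("table total must be at least 10")
  n00 <- tab[1, 1]; n01 <- tab[1, 2]; n10 <- tab[2, 1]; n11 <- tab[2, 2]

  # perfect concordance / discordance on the latent scale: boundary clip
  if (n01 == 0 && n10 == 0)
    return(.tetra_boundary(tab, 1 - .RHO_EPS))
  if (n00 == 0 && n11 == 0)
    return(.tetra_boundary(tab, -(1 - .RHO_EPS)))

  cc <- tab
  cc[cc == 0] <- 0.5            # continuity correction on zero cells
  n <- sum(cc)
  px <- (cc[2, 1] + cc[2, 2]) / n   # P(x = 1)
  py <- (cc[1, 2] + cc[2, 2]) / n   # P(y = 1)
  if (px <= 0 || px >= 1 || py <= 0 || py >= 1)
    stop("degenerate margin: threshold undefined even after continuity correction")
  tau_x <- qnorm(1 - px)
  tau_y <- qnorm(1 - py)

  negll <- function(rho) -.tetra_loglik(cc, tau_x, tau_y, rho)
  opt <- optimize(negll, interval = c(-1 + .RHO_EPS, 1 - .RHO_EPS), tol = 1e-9)
  rho <- opt$minimum
  structure(list(rho = rho, tau_x = tau_x, tau_y = tau_y,
                 loglik = -opt$objective, converged = TRUE,
                 table = tab),
            class = "tetra_estimate")
}

.tetra_boundary <- function(tab, rho) {
  cc <- tab; cc[cc == 0] <- 0.5; n <- sum(cc)
  tau_x <- qnorm(1 - (cc[2, 1] + cc[2, 2]) / n)
  tau_y <- qnorm(1 - (cc[1, 2] + cc[2, 2]) / n)
  structure(list(rho = rho, tau_x = tau_x, tau_y = tau_y,
                 loglik = .tetra_loglik(cc, tau_x, tau_y, rho),
                 converged = FALSE, table = tab),
            class = "tetra_estimate")
}

# multinomial log-likelihood of a (continuity-corrected) 2x2 table
.tetra_loglik <- function(cc, tau_x, tau_y, rho) {
  p11 <- .bvnd(tau_x, tau_y, rho)                    # P(x=1, y=1)
  p10 <- pnorm(-tau_x) - p11                         # P(x=1, y=0)
  p01 <- pnorm(-tau_y) - p11
  p00 <- 1 - p11 - p10 - p01
  p <- pmax(c(p00, p01, p10, p11), 1e-12)
  sum(c(cc[1, 1], cc[1, 2], cc[2, 1], cc[2, 2]) * log(p))
}

#' @export
print.tetra_estimate <- function(x, ...) {
  cat(sprintf("tetrachoric rho = %.4f (tau_x = %.3f, tau_y = %.3f, loglik = %.2f%s)\n",
              x$rho, x$tau_x, x$tau_y, x$loglik,
              if (x$converged) "" else ", boundary"))
  invisible(x)
}

#' Polychoric correlation between two ordinal vectors
#'
#' Two-step maximum likelihood for ordered categorical variables: thresholds
#' from cumulative marginal proportions, latent correlation by 1-D profile
#' likelihood over bivariate-normal cell probabilities. With two categories
#' per variable this is the tetrachoric estimator.
#'
#' @param x,y integer-valued vectors (levels need not be consecutive; they
#'   are ranked).
#' @return list with `rho`, threshold vectors `tau_x`, `tau_y`, `loglik`.
#' @export
polychoric_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xf <- factor(x); yf <- factor(y)
  if (nlevels(xf) < 2 || nlevels(yf) < 2)
    stop("both variables need at least two observed categories")
  tab <- table(xf, yf)
  cc <- unclass(tab) + 0
  cc[cc == 0] <- 0.5
  n <- sum(cc)
  tau_x <- qnorm(cumsum(rowSums(cc))[-nrow(cc)] / n)
  tau_y <- qnorm(cumsum(colSums(cc))[-ncol(cc)] / n)
  ax <- c(-Inf, tau_x, Inf); ay <- c(-Inf, tau_y, Inf)
  negll <- function(rho) {
    P <- matrix(0, nrow(cc), ncol(cc))
    F <- outer(seq_along(ax), seq_along(ay),
               function(i, j) pbvnorm(ax[i], ay[j], rho))
    for (i in seq_len(nrow(cc))) for (j in seq_len(ncol(cc)))
      P[i, j] <- F[i + 1, j + 1] - F[i, j + 1] - F[i + 1, j] + F[i, j]
    -sum(cc * log(pmax(P, 1e-12)))
  }
  opt <- optimize(negll, interval = c(-1 + .RHO_EPS, 1 - .RHO_EPS), tol = 1e-8)
  list(rho = opt$minimum, tau_x = unname(tau_x), tau_y = unname(tau_y),
       loglik = -opt$objective)
}

#' Tetrachoric correlation matrix of item-nonresponse indicators
#'
#' Dichotomizes an item-response matrix to one nonresponse code
#' (`"pna"` = code -3, `"idk"` = code -1), drops degenerate items (all-0 or
#' all-1 indicators, or items that never offer the code) with a warning, and
#' estimates all pairwise tetrachoric correlations. The result is projected
#' to the nearest positive semi-definite correlation matrix when needed.
#'
#' @param items integer matrix/data.frame of coded responses (columns =
#'   items), or an already-binary 0/1 indicator matrix with
#'   `response_code = "binary"`.
#' @param response_code `"pna"`, `"idk"` or `"binary"`.
#' @return correlation matrix with attributes `psd_projection_norm`
#'   (Frobenius norm of the PSD repair, 0 if none) and `dropped` (names of
#'   degenerate items).
#' @export
tetrachoric_matrix <- function(items, response_code = c("pna", "idk", "binary")) {
  response_code <- match.arg(response_code)
  X <- as.matrix(items)
  ind <- switch(response_code,
                pna = (X == -3) * 1L,
                idk = (X == -1) * 1L,
                binary = {
                  if (!all(X %in% c(0, 1))) stop("binary mode expects a 0/1 matrix")
                  X * 1L
                })
  if (is.null(colnames(ind))) colnames(ind) <- paste0("item", seq_len(ncol(ind)))
  rate <- colMeans(ind)
  keep <- rate > 0 & rate < 1
  if (!any(keep)) stop("all items are degenerate (constant indicator): ",
                       paste(colnames(ind), collapse = ", "))
  if (any(!keep))
    warning("dropping degenerate items: ",
            paste(colnames(ind)[!keep], collapse = ", "))
  ind <- ind[, keep, drop = FALSE]
  q <- ncol(ind)
  if (q < 2) stop("need at least 2 non-degenerate items")

  # all pairwise 2x2 tables at once via cross-products
  n <- nrow(ind)
  c11 <- crossprod(ind)                 # both 1
  m1 <- colSums(ind)
  R <- diag(1, q)
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      n11 <- c11[i, j]
      n10 <- m1[i] - n11
      n01 <- m1[j] - n11
      n00 <- n - n11 - n10 - n01
      est <- tetrachoric_rho(matrix(c(n00, n01, n10, n11), 2, byrow = TRUE))
      R[i, j] <- R[j, i] <- est$rho
    }
  }
  dimnames(R) <- list(colnames(ind), colnames(ind))
  out <- nearest_psd(R)
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}

#' Project a symmetric matrix to the nearest PSD correlation matrix
#'
#' Eigenvalue clipping at 1e-8 followed by diagonal renormalization. The
#' Frobenius norm of the adjustment is recorded in attribute
#' `psd_projection_norm`.
#'
#' @param R symmetric matrix with unit diagonal.
#' @return repaired matrix.
#' @export
nearest_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values >= 1e-8)) {
    attr(R, "psd_projection_norm") <- 0
    return(R)
  }
  v <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2 <- (R2 + t(R2)) / 2
  dimnames(R2) <- dimnames(R)
  attr(R2, "psd_projection_norm") <- sqrt(sum((R2 - R)^2))
  R2
}

#' Write / read a correlation matrix as TSV with item identifiers
#' @param R matrix with dimnames.
#' @param path file path.
#' @export
write_corr_matrix <- function(R, path) {
  df <- data.frame(item = rownames(R), R, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corr_matrix
#' @export
read_corr_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  R <- as.matrix(df[, -1, drop = FALSE])
  rownames(R) <- df[[1]]
  R
}
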