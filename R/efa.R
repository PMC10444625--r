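# Exploratory factor analysis: minimum-residual (OLS) extraction and
# gradient-projection oblique rotation.
#
# The rotation criterion named "biquartimin" applies the quartimin
# (oblimin, gamma = 0) complexity criterion to all factors except the
# first, leaving the first column free to act as a general factor
# (Jennrich & Bentler's bifactor rotation family). Optimization follows
# the Bernaards & Jennrich gradient-projection algorithm, run on the
# orthogonal manifold (see .gpf_rotate_multi for why).

# minres/OLS extraction: minimize off-diagonal squared residuals over
# uniquenesses, loadings from the truncated eigen decomposition.
.minres_extract <- function(R, k) {
  p <- ncol(R)
  if (sum(R[upper.tri(R)]^2) < 1e-12) {
    # (near-)diagonal input: the off-diagonal objective is flat; report the
    # null-loading solution rather than an arbitrary degenerate one
    return(list(loadings = matrix(0, p, k), uniquenesses = rep(1, p),
                objective = 0, converged = TRUE))
  }
  load_from_psi <- function(psi) {
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    v <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(v), k)
  }
  obj <- function(psi) {
    L <- load_from_psi(psi)
    res <- R - tcrossprod(L)
    sum(res[upper.tri(res)]^2)
  }
  # start at 1 - squared multiple correlation
  start <- 1 / pmax(diag(solve(nearest_psd(R) + diag(1e-6, p))), 1)
  start <- pmin(pmax(start, 0.05), 0.999)
  fit <- nlminb(start, obj, lower = 1e-3, upper = 1)
  L <- load_from_psi(fit$par)
  # sign convention: majority-positive columns
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, `*`)
  list(loadings = L, uniquenesses = fit$par, objective = fit$objective,
       converged = fit$convergence == 0)
}

# quartimin criterion restricted to non-first columns (first = general)
.vgQ_biquartimin <- function(L) {
  k <- ncol(L)
  L2 <- L[, -1, drop = FALSE]
  M <- matrix(1, k - 1, k - 1) - diag(k - 1)
  X <- L2^2 %*% M
  list(f = sum(L2^2 * X) / 4, Gq = cbind(0, L2 * X))
}

# quartimin on all columns (used when no general column is reserved)
.vgQ_quartimin <- function(L) {
  k <- ncol(L)
  M <- matrix(1, k, k) - diag(k)
  X <- L^2 %*% M
  list(f = sum(L^2 * X) / 4, Gq = L * X)
}

# Bifactor rotation with restarts. The rotation runs on the orthogonal
# manifold: the oblique variant of this criterion has degenerate minima in
# which a group factor is absorbed into the factor correlations, whereas
# with orthogonal factors the criterion minimum on bifactor-structured data
# is the generative pattern. Restarts are deterministic; the best criterion
# value whose leading column still loads on every item wins, which guards
# against collapsed solutions on noisy matrices.
.gpf_rotate_multi <- function(A, vgQ, n_starts = 10, maxit = 3000, eps = 1e-6) {
  k <- ncol(A)
  general_strength <- function(fit) {
    L <- fit$loadings
    min(abs(L[, which.max(colMeans(abs(L)))]))
  }
  pick <- function(a, b) {
    if (is.null(b)) return(a)
    ga <- general_strength(a) >= 0.1
    gb <- general_strength(b) >= 0.1
    if (ga != gb) return(if (ga) a else b)
    if (a$f <= b$f) a else b
  }
  best <- .gpf_orth(A, vgQ, diag(k), maxit, eps)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(20240811L)
  for (i in seq_len(n_starts - 1)) {
    T0 <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
    cand <- tryCatch(.gpf_orth(A, vgQ, T0, maxit, eps),
                     error = function(e) NULL)
    if (!is.null(cand)) best <- pick(best, cand)
  }
  best
}

# Gradient-projection orthogonal rotation (Bernaards & Jennrich 2005).
.gpf_orth <- function(A, vgQ, Tmat = diag(ncol(A)), maxit = 1000, eps = 1e-6) {
  al <- 1
  L <- A %*% Tmat
  VgQ <- vgQ(L)
  f <- VgQ$f
  G <- crossprod(A, VgQ$Gq)
  s <- Inf
  for (iter in seq_len(maxit)) {
    M <- crossprod(Tmat, G)
    Gp <- G - Tmat %*% ((M + t(M)) / 2)
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 1:25) {
      X <- Tmat - al * Gp
      sv <- svd(X)
      Tt <- sv$u %*% t(sv$v)
      L <- A %*% Tt
      VgQt <- vgQ(L)
      if (VgQt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- VgQt$f
    G <- crossprod(A, VgQt$Gq)
  }
  list(loadings = L, Phi = diag(ncol(A)), f = f, converged = s < eps,
       iterations = iter)
}

# Gradient-projection oblique rotation (Bernaards & Jennrich 2005).
.gpf_oblq <- function(A, vgQ, Tmat = diag(ncol(A)), maxit = 1000, eps = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  VgQ <- vgQ(L)
  f <- VgQ$f
  G <- -t(t(L) %*% VgQ$Gq %*% Ti)
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 1:25) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)))
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      VgQt <- vgQ(L)
      if (VgQt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- VgQt$f
    G <- -t(t(L) %*% VgQt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, f = f, converged = s < eps,
       iterations = iter)
}

#' Single-factor exploratory factor analysis
#'
#' Minimum-residual (ordinary least squares) extraction of one factor from a
#' correlation matrix; the residual matrix (off-diagonal of `R - LL'`) feeds
#' the residual clustering stage.
#'
#' @param corr PSD correlation matrix.
#' @return object of class `"efa_result"`: loadings (p x 1), `residuals`
#'   (diagonal zeroed), `uniquenesses`, `extraction = "minres"`,
#'   `rotation = "none"`, `heywood` flag.
#' @export
efa_single_factor <- function(corr) {
  R <- as.matrix(corr)
  ext <- .minres_extract(R, 1)
  L <- ext$loadings
  heywood <- any(rowSums(L^2) > 1 + 1e-8)
  if (heywood) {
    warning("Heywood case: communality > 1; loading clipped")
    L <- sign(L) * pmin(abs(L), 1)
  }
  res <- R - tcrossprod(L)
  diag(res) <- 0
  rownames(L) <- rownames(res)
  structure(list(loadings = L, residuals = res,
                 uniquenesses = ext$uniquenesses,
                 factor_correlations = matrix(1, 1, 1),
                 extraction = "minres", rotation = "none",
                 heywood = heywood, converged = ext$converged),
            class = "efa_result")
}

#' Bifactor-style exploratory factor analysis
#'
#' Extracts `n_group_factors + 1` factors by minres and applies the bifactor
#' ("biquartimin") rotation: the quartimin complexity criterion on the group
#' columns with the first column left unconstrained as the general factor,
#' rotated on the orthogonal manifold. The general column is re-identified
#' after rotation as the factor with the broadest absolute loadings and is
#' sign-aligned to be positive.
#'
#' @param corr PSD correlation matrix.
#' @param n_group_factors number of group factors (>= 2).
#' @return `"efa_result"` with `loadings` (general factor first column),
#'   `factor_correlations`, `residuals`.
#' @export
efa_bifactor <- function(corr, n_group_factors) {
  if (n_group_factors < 2) stop("n_group_factors must be >= 2")
  R <- as.matrix(corr)
  k <- n_group_factors + 1L
  if (k >= ncol(R)) stop("too many factors for ", ncol(R), " items")
  ext <- .minres_extract(R, k)
  rot <- .gpf_rotate_multi(ext$loadings, .vgQ_biquartimin)
  if (!rot$converged)
    warning("biquartimin rotation did not reach tolerance after ",
            rot$iterations, " iterations")
  L <- rot$loadings
  # identify the general column: largest minimum |loading| breadth
  breadth <- apply(abs(L), 2, function(x) mean(x))
  gcol <- which.max(breadth)
  ord <- c(gcol, setdiff(seq_len(k), gcol))
  L <- L[, ord, drop = FALSE]
  Phi <- rot$Phi[ord, ord, drop = FALSE]
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, `*`)
  Phi <- diag(sgn) %*% Phi %*% diag(sgn)
  res <- R - L %*% Phi %*% t(L)
  diag(res) <- 0
  rownames(L) <- rownames(R)
  colnames(L) <- c("general", paste0("group", seq_len(k - 1)))
  structure(list(loadings = L, residuals = res,
                 uniquenesses = ext$uniquenesses,
                 factor_correlations = Phi,
                 extraction = "minres", rotation = "biquartimin",
                 heywood = any(rowSums(L^2) > 1 + 1e-8),
                 converged = ext$converged && rot$converged),
            class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("EFA (%s extraction, %s rotation): %d items, %d factor(s)\n",
              x$extraction, x$rotation, nrow(x$loadings), ncol(x$loadings)))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Derive a bifactor zero-constraint pattern from EFA loadings
#'
#' Items load on the general factor always; an item joins the group factor
#' where its rotated |loading| is largest, provided it passes the magnitude
#' cutoff. Group factors left with fewer than `min_items` items are dropped.
#'
#' @param efa an [efa_bifactor()] result.
#' @param cutoff magnitude threshold (default 0.30).
#' @param min_items minimum items per retained group factor.
#' @return logical items x groups matrix (TRUE = free loading).
#' @export
bifactor_pattern <- function(efa, cutoff = 0.30, min_items = 3) {
  L <- efa$loadings
  G <- abs(L[, -1, drop = FALSE])
  pat <- matrix(FALSE, nrow(L), ncol(G), dimnames = dimnames(G))
  if (ncol(G) > 0) {
    best <- max.col(G, ties.method = "first")
    hit <- G[cbind(seq_len(nrow(G)), best)] >= cutoff
    pat[cbind(which(hit), best[hit])] <- TRUE
    keep <- colSums(pat) >= min_items
    pat <- pat[, keep, drop = FALSE]
  }
  pat
}
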