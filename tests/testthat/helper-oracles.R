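# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# exact bifactor correlation matrix from loadings
bifactor_corr <- function(general, domain_loading, domains) {
  p <- length(general)
  k <- max(domains)
  Gd <- matrix(0, p, k)
  Gd[cbind(seq_len(p), domains)] <- domain_loading
  L <- cbind(general, Gd)
  R <- tcrossprod(L)
  diag(R) <- 1
  dimnames(R) <- list(paste0("it", 1:p), paste0("it", 1:p))
  R
}

# two-stage grid-search tetrachoric oracle built on mvtnorm rectangle
# probabilities (coarse 0.01 grid, then 1e-4 grid in a +/-0.02 window)
tetra_grid_oracle <- function(tab) {
  cc <- tab
  cc[cc == 0] <- 0.5
  n <- sum(cc)
  tx <- qnorm(1 - (cc[2, 1] + cc[2, 2]) / n)
  ty <- qnorm(1 - (cc[1, 2] + cc[2, 2]) / n)
  ll <- function(rho) {
    p11 <- mvtnorm::pmvnorm(lower = c(tx, ty), upper = c(Inf, Inf),
                            corr = matrix(c(1, rho, rho, 1), 2))[1]
    p10 <- pnorm(-tx) - p11
    p01 <- pnorm(-ty) - p11
    p00 <- 1 - p11 - p10 - p01
    sum(c(cc[1, 1], cc[1, 2], cc[2, 1], cc[2, 2]) *
          log(pmax(c(p00, p01, p10, p11), 1e-12)))
  }
  g1 <- seq(-0.99, 0.99, by = 0.01)
  r0 <- g1[which.max(vapply(g1, ll, numeric(1)))]
  g2 <- seq(max(-0.9999, r0 - 0.02), min(0.9999, r0 + 0.02), by = 1e-4)
  g2[which.max(vapply(g2, ll, numeric(1)))]
}

# sample a 2x2 table from a latent bivariate normal
sample_tetra_table <- function(n, rho, tx = 0, ty = 0) {
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  bx <- as.integer(x > tx)
  by <- as.integer(y > ty)
  matrix(c(sum(bx == 0 & by == 0), sum(bx == 0 & by == 1),
           sum(bx == 1 & by == 0), sum(bx == 1 & by == 1)),
         2, byrow = TRUE)
}

# independent greedy clumping re-derivation for tiny instances, written
# with explicit set bookkeeping (checks the packaged implementation)
clump_bruteforce <- function(res, ld, p_thresh = 5e-8, r2_lead = 0.1,
                             r2_member = 0.6, window = 250000) {
  remaining <- seq_len(nrow(res))
  leads <- integer(0)
  out <- list()
  ord <- order(res$p)
  for (i in ord) {
    if (!(i %in% remaining)) next
    if (res$p[i] >= p_thresh) next
    if (any(ld[i, leads] >= r2_lead)) next
    mem <- remaining[res$chr[remaining] == res$chr[i] &
                       abs(res$pos[remaining] - res$pos[i]) <= window &
                       ld[remaining, i] > r2_member]
    mem <- sort(union(i, mem))
    remaining <- setdiff(remaining, mem)
    leads <- c(leads, i)
    out[[length(out) + 1]] <- list(lead = res$snp[i],
                                   members = sort(res$snp[mem]))
  }
  out
}

# Haseman-Elston style SNP-heritability estimate from standardized
# genotypes (off-diagonal GRM regression, computed without forming the GRM)
he_h2 <- function(G, y) {
  Gs <- scale(G)
  m <- ncol(Gs)
  yKy <- sum((crossprod(Gs, y))^2) / m
  diagK <- rowSums(Gs^2) / m
  num <- yKy - sum(diagK * y^2)
  GtG <- crossprod(Gs) / m
  den <- sum(GtG^2) - sum(diagK^2)
  num / den
}
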