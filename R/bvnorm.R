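# Bivariate standard normal probabilities.
#
# Gauss-Legendre quadrature after Drezner & Wesolowsky as refined by Genz
# (TVPACK BVND): the |rho| <= 0.925 branch integrates over sin-transformed
# correlation, the near-singular branch uses the complementary expansion.
# Absolute accuracy ~1e-15, adequate for likelihood work at any table size.

# Nodes/weights for 6-, 12- and 20-point Gauss-Legendre rules (half tables).
.gl_w <- list(
  c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
  c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
    0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
  c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
    0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
    0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
    0.1527533871307259))
.gl_x <- list(
  c(-0.9324695142031522, -0.6612093864662647, -0.2386191860831970),
  c(-0.9815606342467191, -0.9041172563704750, -0.7699026741943050,
    -0.5873179542866171, -0.3678314989981802, -0.1252334085114692),
  c(-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
    -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
    -0.5108670019508271, -0.3737060887154196, -0.2277858511416451,
    -0.07652652113349733))

# P(X > dh, Y > dk) for standard bivariate normal with correlation r (scalar).
.bvnd <- function(dh, dk, r) {
  if (is.na(dh) || is.na(dk) || is.na(r)) return(NA_real_)
  if (dh == Inf || dk == Inf) return(0)
  if (dh == -Inf) return(pnorm(dk, lower.tail = FALSE))
  if (dk == -Inf) return(pnorm(dh, lower.tail = FALSE))
  if (r >= 1)  return(pnorm(max(dh, dk), lower.tail = FALSE))
  if (r <= -1) return(max(0, pnorm(-dk) - pnorm(dh)))
  twopi <- 2 * pi
  ng <- if (abs(r) < 0.3) 1L else if (abs(r) < 0.75) 2L else 3L
  w <- .gl_w[[ng]]; x <- .gl_x[[ng]]
  h <- dh; k <- dk; hk <- h * k; bvn <- 0
  if (abs(r) < 0.925) {
    if (abs(r) > 0) {
      hs <- (h * h + k * k) / 2
      asr <- asin(r)
      sn1 <- sin(asr * (1 - x) / 2)
      sn2 <- sin(asr * (1 + x) / 2)
      bvn <- sum(w * exp((sn1 * hk - hs) / (1 - sn1^2))) +
             sum(w * exp((sn2 * hk - hs) / (1 - sn2^2)))
      bvn <- bvn * asr / (2 * twopi)
    }
    bvn + pnorm(-h) * pnorm(-k)
  } else {
    if (r < 0) { k <- -k; hk <- -hk }
    if (abs(r) < 1) {
      as_ <- (1 - r) * (1 + r); a <- sqrt(as_); bs <- (h - k)^2
      cc <- (4 - hk) / 8; dd <- (12 - hk) / 16
      asr <- -(bs / as_ + hk) / 2
      if (asr > -100)
        bvn <- a * exp(asr) *
          (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 + cc * dd * as_^2 / 5)
      if (-hk < 100) {
        b <- sqrt(bs)
        bvn <- bvn - exp(-hk / 2) * sqrt(twopi) * pnorm(-b / a) * b *
          (1 - cc * bs * (1 - dd * bs / 5) / 3)
      }
      a <- a / 2
      for (i in seq_along(x)) {
        for (is_ in c(-1, 1)) {
          xs <- (a * (is_ * x[i] + 1))^2
          rs <- sqrt(1 - xs)
          asr <- -(bs / xs + hk) / 2
          if (asr > -100) {
            bvn <- bvn + a * w[i] * exp(asr) *
              (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
                 (1 + cc * xs * (1 + dd * xs)))
          }
        }
      }
      bvn <- -bvn / twopi
    }
    if (r > 0) {
      bvn + pnorm(-max(h, k))
    } else {
      bvn <- -bvn
      if (k > h) bvn <- bvn + pnorm(k) - pnorm(h)
      bvn
    }
  }
}

#' Bivariate standard normal CDF
#'
#' `pbvnorm(h, k, rho)` returns `P(X <= h, Y <= k)` for standard bivariate
#' normal `(X, Y)` with correlation `rho`. Vectorized over all arguments
#' (recycled). Used internally by the tetrachoric/polychoric likelihoods,
#' exported because rectangle probabilities are handy for oracle work.
#'
#' @param h,k upper integration limits.
#' @param rho correlation(s) in `[-1, 1]`.
#' @return numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0)    # 0.25
#' pbvnorm(0, 0, 0.5)  # 1/4 + asin(0.5)/(2*pi) = 1/3
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- .bvnd(-h[i], -k[i], rho[i])
  pmin(pmax(out, 0), 1)
}
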