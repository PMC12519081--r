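# Independent oracles and fixture builders used across test files.

# Random positive-definite covariance (Wishart-style, well-conditioned).
random_pd_sigma <- function(p, n = 4 * p) {
  x <- matrix(rnorm(n * p), n, p)
  crossprod(x) / n + diag(0.2, p)
}

# Adjusted Rand index by brute-force pair counting: classify all n*(n-1)/2
# item pairs as together/apart in each partition and apply the pair-count
# identity ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)). Independent of any
# contingency-table implementation.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)  # both partitions degenerate
  2 * (n11 * n00 - n10 * n01) / den
}

# Equicorrelated-covariance O-information closed form (unit variances).
oinfo_equicorr <- function(rho, k = 3) {
  det_full <- (1 - rho)^(k - 1) * (1 + (k - 1) * rho)
  det_minor <- (1 - rho)^(k - 2) * (1 + (k - 2) * rho)
  0.5 * ((k - 2) * log(det_full) - k * log(det_minor))
}

# Monte-Carlo plug-in estimate of O-info from a large Gaussian sample.
oinfo_mc <- function(sigma, n = 1e5, seed = 1) {
  p <- ncol(sigma)
  L <- chol(sigma)
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p) %*% L)
  as.double(o_info(covariance_model(cov(x))))
}
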