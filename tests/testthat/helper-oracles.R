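## Shared fixtures and independent oracles used across the test files.
## Everything is generated in code; no stored data.

## Brute-force greedy LD pruning oracle: a direct re-statement of the rule
## (visit by priority, keep iff no kept partner exceeds the r^2 threshold)
## kept deliberately naive and separate from the package implementation.
prune_oracle <- function(R, priority, kappa2) {
  m <- nrow(R)
  ord <- order(priority, seq_len(m))
  kept <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (k in kept) if (R[j, k]^2 > kappa2) { ok <- FALSE; break }
    if (ok) kept <- c(kept, j)
  }
  sort(kept)
}

## random correlation matrix of dimension d (PSD by construction)
random_corr <- function(d) {
  A <- matrix(rnorm(d * (d + 2L)), d)
  cov2cor(tcrossprod(A) + diag(d) * 1e-6)
}

## Expected genotype correlation under the latent-Gaussian copula: alleles
## are indicators {latent < qnorm(maf)} with latent correlation a; the
## genotype correlation equals the allele-indicator correlation. P(both
## alleles minor) is computed by one-dimensional quadrature over the
## conditional normal, independently of the package's sampling code.
copula_genotype_corr <- function(a, maf) {
  thr <- qnorm(maf)
  p11 <- integrate(function(z)
    pnorm((thr - a * z) / sqrt(1 - a^2)) * dnorm(z),
    lower = -Inf, upper = thr)$value
  (p11 - maf^2) / (maf * (1 - maf))
}

## Monte-Carlo oracle for the overlapping-sample error covariance: two
## phenotypes with correlation rho measured on partially shared samples,
## no genetic effects, per-SNP OLS slopes; the empirical covariance of the
## two estimation errors is the quantity errorCovariance() predicts.
overlap_cov_oracle <- function(nA, nB, nShared, rho, nSNP) {
  ntot <- nA + nB - nShared
  G <- matrix(rnorm(ntot * nSNP), ntot)
  z1 <- rnorm(ntot)
  y1 <- z1
  y2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(ntot)
  A <- seq_len(nA)
  B <- c(seq_len(nShared), nA + seq_len(nB - nShared))
  bA <- as.numeric(crossprod(G[A, ], y1[A])) / colSums(G[A, ]^2)
  bB <- as.numeric(crossprod(G[B, ], y2[B])) / colSums(G[B, ]^2)
  cov(bA, bB)
}

## quick univariable summary parameter bundle used by several files
quick_params <- function(...) {
  args <- list(...)
  defaults <- list(theta = 0.2, M = 100, nx = 5e4, nY = 5e4, h = 0.3,
                   seed = 1L)
  do.call(summaryParams, utils::modifyList(defaults, args))
}
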