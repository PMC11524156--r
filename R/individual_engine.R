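## Individual-level engine: simulate standardized genotypes, a confounder,
## exposures and an outcome from the structural model
##   U = g'gammaC + epsU
##   x = B'g + piX U + epsX
##   Y = x'theta + piY U + g'gammaU + epsY
## then run per-SNP OLS GWAS on overlapping exposure/outcome samples.

#' Draw standardized genotypes
#'
#' Each SNP is marginally Binomial(2, maf). With an LD matrix `R` the two
#' allele draws per SNP come from a latent Gaussian copula: latent
#' `MVN(0, R)` rows are thresholded at the maf quantile, so the realized
#' genotype correlation slightly attenuates the latent correlation (the
#' attenuation is measured by the test suite rather than corrected).
#' Columns are standardized to sample mean 0 and variance 1 unless
#' `standardize = FALSE`.
#'
#' @param n number of individuals (>= 2).
#' @param M number of SNPs.
#' @param maf allele frequency in (0, 0.5].
#' @param R optional M x M LD correlation matrix.
#' @param standardize standardize columns empirically (default TRUE).
#' @return n x M genotype matrix.
#' @export
drawGenotypes <- function(n, M, maf = 0.3, R = NULL, standardize = TRUE) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (is.null(R) || isIdentity(R)) {
    G <- matrix(stats::rbinom(n * M, 2L, maf), n, M)
  } else {
    if (nrow(R) != M) stop("R must be M x M", call. = FALSE)
    thr <- stats::qnorm(maf)
    U <- matSqrt(R)
    a1 <- (matrix(stats::rnorm(n * M), n, M) %*% U) < thr
    a2 <- (matrix(stats::rnorm(n * M), n, M) %*% U) < thr
    G <- a1 + a2
    storage.mode(G) <- "double"
  }
  if (!standardize) return(G)
  sds <- apply(G, 2L, stats::sd)
  if (any(sds == 0))
    stop("monomorphic SNP drawn (zero variance); increase n or maf",
         call. = FALSE)
  scale(G, center = TRUE, scale = sds)[, , drop = FALSE]
}

## shared helper for the two pleiotropy draws: Uniform(-1,1) raw effects on
## a contiguous support, jointly rescaled against the realized genotype
## covariance so the component g' gamma explains exactly `sigma2` variance
drawScaledPleiotropy <- function(G, m, sigma2, offset) {
  M <- ncol(G)
  if (offset + m > M) stop("pleiotropy support exceeds M", call. = FALSE)
  out <- numeric(M)
  if (m < 1L || sigma2 == 0) return(out)
  raw <- stats::runif(m, -1, 1)
  idx <- offset + seq_len(m)
  comp <- G[, idx, drop = FALSE] %*% raw
  v <- stats::var(as.numeric(comp))
  if (v <= 0) stop("degenerate pleiotropy draw", call. = FALSE)
  out[idx] <- raw * sqrt(sigma2 / v)
  out
}

#' Draw UHP effects for the individual-level engine
#'
#' SNPs `1..mU` receive Uniform(-1, 1) direct-on-outcome effects, jointly
#' rescaled under the realized genotype covariance so that `g' gammaU`
#' explains exactly `sigma2GammaU` of the (unit) outcome variance.
#'
#' @param G standardized genotype matrix.
#' @param mU number of UHP SNPs.
#' @param sigma2GammaU variance in Y explained by the UHP SNPs.
#' @return M-vector of UHP path coefficients.
#' @export
drawUHPIndividual <- function(G, mU, sigma2GammaU) {
  drawScaledPleiotropy(G, mU, sigma2GammaU, offset = 0L)
}

#' Draw CHP effects for the individual-level engine
#'
#' SNPs `mU+1..mU+mC` (disjoint from the UHP group) receive Uniform(-1, 1)
#' effects on the confounder U, rescaled so that `g' gammaC` explains
#' exactly `sigma2GammaC` of the (unit) confounder variance.
#'
#' @param G standardized genotype matrix.
#' @param mC number of CHP SNPs.
#' @param sigma2GammaC variance in U explained by the CHP SNPs.
#' @param mU number of UHP SNPs (start of the CHP block).
#' @return M-vector of CHP path coefficients.
#' @export
drawCHPIndividual <- function(G, mC, sigma2GammaC, mU = 0L) {
  drawScaledPleiotropy(G, mC, sigma2GammaC, offset = as.integer(mU))
}

#' Draw SNP-exposure path coefficients with exact heritability
#'
#' Matrix-normal draw with row covariance `R` and column covariance
#' `diag(sqrt(h)) %*% Rbb %*% diag(sqrt(h)) / M`, followed by an exact
#' column rescale so that `diag(B'B)[k] == h[k]` to machine precision.
#' A zero heritability gives a zero column.
#'
#' @param M number of SNPs.
#' @param h p-vector of exposure heritabilities.
#' @param Rbb p x p genetic correlation matrix.
#' @param R optional M x M LD matrix.
#' @return M x p coefficient matrix.
#' @export
drawExposureEffectsMatrix <- function(M, h, Rbb, R = NULL) {
  p <- length(h)
  D <- diag(sqrt(h), p)
  B <- drawTrueExposureEffects(M, D %*% Rbb %*% D, R)
  for (k in seq_len(p)) {
    ss <- sum(B[, k]^2)
    B[, k] <- if (h[k] == 0 || ss == 0) 0 else B[, k] * sqrt(h[k] / ss)
  }
  B
}

#' Solve the structural model by moment matching
#'
#' Determines all path coefficients and residual scales so that U, every
#' exposure and the outcome have variance exactly 1, `Cov(x | U)` matches
#' `params@covXU`, and `Var(Y | U, x_k)` matches `params@varYUX` for each
#' exposure. Confounder-to-exposure effects have the closed form
#' `piX_k = sqrt(1 - covXU[k,k]) - Cov(b_k'g, U)`; the causal-effect
#' magnitudes and the confounder-to-outcome path `piY` are solved jointly
#' from the p conditional-variance equations (with the outcome residual
#' variance substituted as the unit-variance slack). Because those
#' equations identify `piY` only up to a one-dimensional trade-off with
#' the outcome residual, `piY` is anchored at its initialization -1 scaled
#' back by the exposures' average confounded share,
#' `-sqrt(mean(1 - diag(covXU)))` (zero when the exposures are
#' unconfounded), and the solution closest to that anchor is taken.
#' Infeasible variance budgets (any negative residual variance) raise an
#' error naming the violated component.
#'
#' @param params an [IndividualParams-class] object.
#' @param B M x p SNP-exposure coefficients (see
#'   [drawExposureEffectsMatrix()]).
#' @param gammaU,gammaC M-vectors of pleiotropy coefficients.
#' @return a [StructuralModel-class] object.
#' @export
buildStructuralModel <- function(params, B, gammaU, gammaC) {
  stopifnot(is(params, "IndividualParams"))
  R <- params@R; C <- params@covXU; tY <- params@varYUX
  p <- params@p
  RgC <- as.numeric(R %*% gammaC)
  RgU <- as.numeric(R %*% gammaU)
  vCg <- sum(gammaC * RgC)              # Var(g' gammaC)
  if (vCg > 1 + 1e-8)
    stop("infeasible model: CHP SNPs explain more than the unit variance ",
         "of U (sigma2GammaC too large)", call. = FALSE)
  residSdU <- sqrt(max(0, 1 - vCg))

  cB <- as.numeric(crossprod(B, RgC))   # Cov(b_k'g, U)
  q <- sqrt(1 - diag(C))                # Cov(x_k, U)
  piX <- q - cB
  v <- crossprod(B, R %*% B)            # Cov(b_k'g, b_l'g)
  SigmaXX <- C + tcrossprod(q)          # total exposure covariance
  SigmaEpsX <- SigmaXX - v - tcrossprod(piX) -
    outer(piX, cB) - outer(cB, piX)
  SigmaEpsX <- (SigmaEpsX + t(SigmaEpsX)) / 2
  negk <- which(diag(SigmaEpsX) < -1e-8)
  if (length(negk))
    stop("infeasible model: negative residual variance for exposure(s) ",
         paste(negk, collapse = ", "),
         " (heritability + confounding exceed the unit variance budget)",
         call. = FALSE)
  ev <- min(eigen(SigmaEpsX, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6)
    stop("infeasible model: exposure residual covariance is not positive ",
         "semi-definite (check covXU against h and Rbb)", call. = FALSE)

  if (length(params@Rxx)) {
    dev <- max(abs(stats::cov2cor(SigmaXX) - params@Rxx))
    if (dev > 0.02)
      warning("Rxx is inconsistent with the correlations implied by covXU ",
              "(max deviation ", signif(dev, 3),
              "); the covXU-implied correlations are used", call. = FALSE)
  }

  vUg <- sum(gammaU * RgU)              # Var(g' gammaU)
  cUg <- sum(gammaU * RgC)              # Cov(g' gammaU, U)
  cXg <- as.numeric(crossprod(B, RgU)) + piX * cUg  # Cov(g' gammaU, x_k)
  ## anchor for the confounder-to-outcome path: initialized at -1 and
  ## scaled back by the exposures' average confounded share; piY is then
  ## solved jointly with theta, staying as close to this anchor as the
  ## conditional-variance targets allow (the split between piY and the
  ## outcome residual is not identified by the targets alone)
  piY0 <- -sqrt(max(0, mean(1 - diag(C))))

  moments <- function(th, piY) {
    covYU <- sum(th * q) + piY + cUg
    covYx <- as.numeric(SigmaXX %*% th) + piY * q + cXg
    varSys <- as.numeric(t(th) %*% SigmaXX %*% th) + piY^2 + vUg +
      2 * (piY * sum(th * q) + sum(th * cXg) + piY * cUg)
    list(covYU = covYU, covYx = covYx, sigmaY2 = 1 - varSys)
  }
  condVar <- function(th, piY) {
    mo <- moments(th, piY)
    vapply(seq_len(p), function(k) {
      S2 <- matrix(c(1, q[k], q[k], 1), 2L)
      cv <- c(mo$covYU, mo$covYx[k])
      1 - as.numeric(t(cv) %*% solve(S2, cv))
    }, numeric(1))
  }
  obj <- function(par) {
    th <- params@signTheta * abs(par[seq_len(p)])
    piY <- par[p + 1L]
    sum((condVar(th, piY) - tY)^2) + 1e-6 * (piY - piY0)^2
  }
  par0 <- c(sqrt(pmax(1e-6, 1 - tY)), piY0)
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  if (fit$value > 1e-9)
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 10000, reltol = 1e-15))
  theta <- params@signTheta * abs(fit$par[seq_len(p)])
  piY <- fit$par[p + 1L]
  if (sum((condVar(theta, piY) - tY)^2) > 1e-8)
    stop("infeasible model: could not match Var(Y | U, x_k) targets ",
         "(residual sum of squares ", format(fit$value),
         "); the requested varYUX may be incompatible with covXU, h and ",
         "the pleiotropy shares", call. = FALSE)
  mo <- moments(theta, piY)
  if (mo$sigmaY2 < -1e-8)
    stop("infeasible model: negative residual variance for the outcome ",
         "(varYUX targets too small for the requested confounding and ",
         "pleiotropy)", call. = FALSE)
  residSdY <- sqrt(max(0, mo$sigmaY2))

  ## marginal (GWAS-scale) per-SNP associations
  Bmarg <- R %*% B + outer(RgC, piX)
  gammaUMarg <- RgU
  gammaCMarg <- (sum(theta * piX) + piY) * RgC
  alphaMarg <- as.numeric(Bmarg %*% theta) + gammaUMarg + gammaCMarg

  new("StructuralModel", B = B, gammaU = gammaU, gammaC = gammaC,
      piX = piX, piY = piY, theta = theta,
      residSdU = residSdU, residSdY = residSdY, SigmaEpsX = SigmaEpsX,
      implied = list(SigmaXX = SigmaXX, covXU = q, covYU = mo$covYU,
                     covYx = mo$covYx, sigmaY2 = mo$sigmaY2,
                     Bmarg = Bmarg, gammaUMarg = gammaUMarg,
                     gammaCMarg = gammaCMarg, alphaMarg = alphaMarg,
                     condVar = condVar(theta, piY)))
}

#' Simulate phenotypes from a solved structural model
#'
#' Generates the confounder, exposures and outcome exactly by the three
#' structural equations with independent Gaussian residuals at the solved
#' scales.
#'
#' @param G n x M standardized genotype matrix.
#' @param model a [StructuralModel-class] object.
#' @return a [PhenotypeSet-class] with `x` (n x p), `Y` and `U`.
#' @export
simulatePhenotypes <- function(G, model) {
  n <- nrow(G); p <- length(model@theta)
  U <- as.numeric(G %*% model@gammaC) +
    stats::rnorm(n, 0, model@residSdU)
  Ex <- matrix(stats::rnorm(n * p), n, p) %*% t(matSqrt(model@SigmaEpsX))
  x <- G %*% model@B + tcrossprod(U, model@piX) + Ex
  Y <- as.numeric(x %*% model@theta) + model@piY * U +
    as.numeric(G %*% model@gammaU) +
    stats::rnorm(n, 0, model@residSdY)
  new("PhenotypeSet", x = as.matrix(x), Y = Y, U = U)
}

#' Per-SNP marginal OLS GWAS
#'
#' Simple regression of the phenotype on each SNP separately (with
#' intercept), returning the slope and its OLS standard error with the
#' n - 2 denominator.
#'
#' @param G n x M genotype matrix (the GWAS subsample).
#' @param y n-vector phenotype.
#' @return list with `bhat` and `se`, both M-vectors.
#' @export
runGWAS <- function(G, y) {
  n <- nrow(G)
  if (n < 3) stop("GWAS needs n >= 3", call. = FALSE)
  gm <- colMeans(G)
  ym <- mean(y)
  Sxy <- as.numeric(crossprod(G, y)) - n * gm * ym
  Sxx <- colSums(G^2) - n * gm^2
  if (any(Sxx <= 0))
    stop("zero-variance SNP in the GWAS sample", call. = FALSE)
  bhat <- Sxy / Sxx
  Syy <- sum((y - ym)^2)
  rss <- pmax(0, Syy - bhat^2 * Sxx)
  se <- sqrt(rss / ((n - 2) * Sxx))
  list(bhat = bhat, se = se)
}

#' Generate GWAS summary statistics from individual-level data
#'
#' The individual-level engine: draws genotypes for the union of the
#' exposure and outcome GWAS samples (the two share
#' `round(p01 * min(n0, n1))` individuals; all exposure GWAS share one
#' sample), simulates phenotypes from the solved structural model, runs
#' per-SNP OLS GWAS on the respective subsamples, and applies the same
#' IV-selection, standardization and reference-panel LD stages as
#' [generateSummary()]. The reported error-correlation matrix `rhoME` is
#' the analytic correlation implied by the overlap proportion and the
#' model-implied phenotypic correlations (its role is an input to
#' downstream MR methods, not an estimate from the realization).
#'
#' @param params an [IndividualParams-class] object.
#' @param seed optional override of `params@seed`.
#' @return an [MRDataset-class] object.
#' @export
generateIndividual <- function(params, seed = NULL) {
  stopifnot(is(params, "IndividualParams"))
  seed <- if (is.null(seed)) params@seed else as.integer(seed)
  p <- params@p; M <- params@M
  n1 <- params@n1; n0 <- params@n0
  o <- round(params@p01 * min(n0, n1))
  ntot <- n1 + n0 - o

  G <- withSubstream(seed, "genotypes",
    drawGenotypes(ntot, M, params@maf, params@R))
  gammaU <- withSubstream(seed, "uhp",
    drawUHPIndividual(G, params@mU, params@sigma2GammaU))
  gammaC <- withSubstream(seed, "chp",
    drawCHPIndividual(G, params@mC, params@sigma2GammaC, params@mU))
  B <- withSubstream(seed, "exposure-effects",
    drawExposureEffectsMatrix(M, params@h, params@Rbb, params@R))
  model <- buildStructuralModel(params, B, gammaU, gammaC)
  phen <- withSubstream(seed, "phenotypes", simulatePhenotypes(G, model))

  ## overlap bookkeeping is deterministic: the first o individuals of each
  ## sample are shared; randomness lives in the draws, not the indexing
  Px <- seq_len(n1)
  Py <- c(seq_len(o), n1 + seq_len(n0 - o))

  Gx <- G[Px, , drop = FALSE]
  bxhat <- matrix(0, M, p); bxse <- matrix(0, M, p)
  for (k in seq_len(p)) {
    gw <- runGWAS(Gx, phen@x[Px, k])
    bxhat[, k] <- gw$bhat; bxse[, k] <- gw$se
  }
  gwY <- runGWAS(G[Py, , drop = FALSE], phen@Y[Py])

  ## analytic error correlation from (p01, n0, n1, implied phenotypic
  ## correlations); all exposure GWAS overlap completely
  RxYImp <- rbind(c(1, model@implied$covYx),
                  cbind(model@implied$covYx, model@implied$SigmaXX))
  RxYImp <- stats::cov2cor((RxYImp + t(RxYImp)) / 2)
  ec <- errorCovariance(nx = rep(n1, p), nY = n0,
                        kxY = rep(params@p01, p),
                        Kxx = matrix(1, p, p), RxY = RxYImp)

  truth <- new("TrueEffects",
               B = model@implied$Bmarg,
               gammaU = model@implied$gammaUMarg,
               gammaC = model@implied$gammaCMarg,
               alpha = model@implied$alphaMarg,
               theta = model@theta,
               SigmaBB = crossprod(B),
               ivType = ivTypeLabels(M, params@mU, params@mC))

  assembleDataset(
    Bhat = bxhat, bxse = bxse, alphaHat = gwY$bhat, byse = gwY$se,
    truth = truth, ec = ec, R = params@R, nref = params@nref,
    simType = params@simType, stdType = params@stdType,
    tau = params@tau, kappa2 = params@kappa2, Ftarget = params@Ftarget,
    nx = rep(n1, p), nY = n0, params = params,
    engine = "individual", seed = seed)
}
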