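## Direct generation of GWAS summary statistics from their sampling
## distributions (the fast engine).

#' Draw true SNP-exposure effects
#'
#' Draws the M x p matrix B of true SNP-exposure effects from a matrix
#' normal with row covariance `R` (the LD matrix) and column covariance
#' `SigmaBB / M`, i.e. `vec(B) ~ N(0, (SigmaBB / M) %x% R)`. Column k then
#' has per-SNP variance `h_k / M` so the M SNPs jointly explain
#' heritability `h_k` in expectation. When `R` is the identity (or omitted)
#' the draw reduces to M independent rows from `N(0, SigmaBB / M)`.
#'
#' @param M number of SNPs.
#' @param SigmaBB p x p genetic covariance of the exposures.
#' @param R optional M x M LD correlation matrix.
#' @return M x p matrix of true effects.
#' @export
drawTrueExposureEffects <- function(M, SigmaBB, R = NULL) {
  SigmaBB <- as.matrix(SigmaBB)
  p <- nrow(SigmaBB)
  Z <- matrix(stats::rnorm(M * p), M, p)
  Lc <- matSqrt(SigmaBB / M)
  if (is.null(R) || isIdentity(R)) return(Z %*% t(Lc))
  if (nrow(R) != M) stop("R must be M x M", call. = FALSE)
  Lr <- matSqrt(R)
  Lr %*% Z %*% t(Lc)
}

#' Draw uncorrelated horizontal pleiotropy effects
#'
#' The first `mU` SNPs receive i.i.d. normal direct effects on the outcome
#' with variance `rhoU * t(theta) %*% SigmaBB %*% theta / M`, so that the
#' UHP effects carry a fraction `rhoU` of the variance of the mediated
#' effects `B theta`. All other entries are exactly zero.
#'
#' @param M number of SNPs.
#' @param mU number of UHP SNPs.
#' @param rhoU UHP variance fraction (>= 0).
#' @param theta causal effect vector.
#' @param SigmaBB p x p genetic covariance.
#' @return M-vector of UHP effects.
#' @export
drawUHPEffects <- function(M, mU, rhoU, theta, SigmaBB) {
  if (mU > M) stop("mU cannot exceed M", call. = FALSE)
  out <- numeric(M)
  if (mU < 1L || rhoU == 0) return(out)
  v <- rhoU * as.numeric(t(theta) %*% SigmaBB %*% theta) / M
  out[seq_len(mU)] <- stats::rnorm(mU, 0, sqrt(v))
  out
}

#' Draw correlated horizontal pleiotropy effects
#'
#' SNPs `mU+1 .. mU+mC` (disjoint from the UHP set by construction)
#' receive effects `N(0, rhoC * t(theta) %*% SigmaBB %*% theta / M)` plus
#' the deterministic shift `(B theta) * (-1 + zetaC)` evaluated at the same
#' SNPs, which makes `cor(B theta, gammaC)` negative on the CHP support by
#' default (`zetaC = 1` removes the shift entirely). All other entries are
#' exactly zero, so valid SNPs keep `alpha_j = b_j' theta`.
#'
#' @param M number of SNPs.
#' @param mC number of CHP SNPs.
#' @param rhoC CHP variance fraction (>= 0).
#' @param zetaC sign-correlation control in (-1, 1].
#' @param theta causal effect vector.
#' @param SigmaBB p x p genetic covariance.
#' @param B M x p matrix of true SNP-exposure effects.
#' @param mU number of UHP SNPs (start of the CHP block).
#' @return M-vector of CHP effects.
#' @export
drawCHPEffects <- function(M, mC, rhoC, zetaC, theta, SigmaBB, B, mU = 0L) {
  if (mU + mC > M)
    stop("mU + mC cannot exceed M (supports must be disjoint)",
         call. = FALSE)
  out <- numeric(M)
  if (mC < 1L) return(out)
  idx <- mU + seq_len(mC)
  v <- rhoC * as.numeric(t(theta) %*% SigmaBB %*% theta) / M
  Btheta <- as.numeric(B %*% theta)
  out[idx] <- stats::rnorm(mC, 0, sqrt(v)) + Btheta[idx] * (-1 + zetaC)
  out
}

#' Assemble true SNP-outcome effects
#'
#' The exact identity `alpha = B %*% theta + gammaU + gammaC`.
#'
#' @param B M x p true SNP-exposure effects.
#' @param theta causal effect vector.
#' @param gammaU,gammaC M-vectors of pleiotropy effects.
#' @return M-vector of true SNP-outcome effects.
#' @export
assembleOutcomeEffects <- function(B, theta, gammaU, gammaC) {
  if (ncol(B) != length(theta))
    stop("ncol(B) must equal length(theta)", call. = FALSE)
  if (length(gammaU) != nrow(B) || length(gammaC) != nrow(B))
    stop("gammaU and gammaC must have length nrow(B)", call. = FALSE)
  as.numeric(B %*% theta) + gammaU + gammaC
}

ivTypeLabels <- function(M, mU, mC) {
  c(rep("UHP", mU), rep("CHP", mC), rep("valid", M - mU - mC))
}

#' Generate GWAS summary statistics directly
#'
#' The fast engine: computes the estimation-error covariance implied by the
#' overlap structure, draws true SNP-exposure effects (with LD), UHP and
#' CHP pleiotropy, adds correlated estimation errors and chi-square
#' standard errors, performs IV selection (winner's-curse p-value
#' thresholding with LD pruning, or weak-instrument mean-F calibration),
#' standardizes, and draws the reference-panel-estimated LD matrix of the
#' selected set.
#'
#' @param params a [SummaryParams-class] object.
#' @param seed optional override of `params@seed`.
#' @return an [MRDataset-class] object.
#' @examples
#' ds <- generateSummary(summaryParams(theta = 0.2, M = 100, seed = 3))
#' ds
#' @export
generateSummary <- function(params, seed = NULL) {
  stopifnot(is(params, "SummaryParams"))
  seed <- if (is.null(seed)) params@seed else as.integer(seed)
  p <- params@p; M <- params@M

  ec <- errorCovariance(params@nx, params@nY, params@kxY, params@Kxx,
                        params@RxY)
  D <- diag(sqrt(params@h), p)
  SigmaBB <- D %*% params@Rbb %*% D

  B <- withSubstream(seed, "exposure-effects",
    drawTrueExposureEffects(M, SigmaBB, params@R))
  gammaU <- withSubstream(seed, "uhp",
    drawUHPEffects(M, params@mU, params@rhoU, params@theta, SigmaBB))
  gammaC <- withSubstream(seed, "chp",
    drawCHPEffects(M, params@mC, params@rhoC, params@zetaC, params@theta,
                   SigmaBB, B, params@mU))
  alpha <- assembleOutcomeEffects(B, params@theta, gammaU, gammaC)
  truth <- new("TrueEffects", B = B, gammaU = gammaU, gammaC = gammaC,
               alpha = alpha, theta = params@theta, SigmaBB = SigmaBB,
               ivType = ivTypeLabels(M, params@mU, params@mC))

  err <- withSubstream(seed, "estimation-errors",
    drawEstimationErrors(ec, M))
  alphaHat <- alpha + err$wAlpha
  Bhat <- B + err$Wbeta

  byse <- sqrt(withSubstream(seed, "se-outcome",
    drawSquaredSE(params@nY, M)))
  bxse <- withSubstream(seed, "se-exposures", {
    m <- matrix(0, M, p)
    for (k in seq_len(p)) m[, k] <- sqrt(drawSquaredSE(params@nx[k], M))
    m
  })

  assembleDataset(
    Bhat = Bhat, bxse = bxse, alphaHat = alphaHat, byse = byse,
    truth = truth, ec = ec, R = params@R, nref = params@nref,
    simType = params@simType, stdType = params@stdType,
    tau = params@tau, kappa2 = params@kappa2, Ftarget = params@Ftarget,
    nx = params@nx, nY = params@nY, params = params,
    engine = "summary", seed = seed)
}
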