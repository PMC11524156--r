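## Stochastic components of GWAS estimation: the error covariance Omega
## under sample overlap, Gaussian estimation-error draws, chi-square
## standard-error draws, and Wishart reference-panel LD noise.

## Named RNG substreams: every draw type in the engines runs under its own
## seed derived from (master seed, label), so draws are reproducible and
## mutually stream-independent (drawing more of one type never perturbs
## another type).
subSeed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * (17 + seq_along(v)))
  as.integer((as.numeric(seed) %% 2147483647 * 69621 + h * 7919) %%
               2147483647)
}

withSubstream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(subSeed(seed, label))
  expr
}

#' Covariance of GWAS estimation errors under sample overlap
#'
#' Computes the (p+1) x (p+1) covariance matrix Omega of the standardized
#' per-SNP GWAS estimation errors, outcome in the first row and column.
#' For studies i and j with sample sizes `n_i`, `n_j`, overlap proportion
#' `k_ij` and phenotypic correlation `rho_ij`, the shared-sample count is
#' `n_ij = k_ij * min(n_i, n_j)` and
#' `Omega[i, j] = n_ij * rho_ij / (n_i * n_j)`, with diagonal `1 / n_i`
#' (the sampling variance of a standardized per-SNP OLS estimate). The
#' correlation form RhoME is what downstream MR methods consume.
#'
#' @param nx p-vector of exposure GWAS sample sizes.
#' @param nY outcome GWAS sample size.
#' @param kxY p-vector of exposure-outcome overlap proportions.
#' @param Kxx p x p exposure-exposure overlap proportions (unit diagonal).
#' @param RxY (p+1) x (p+1) phenotypic correlation matrix, outcome first.
#' @return an [ErrorCovariance-class] object.
#' @examples
#' ec <- errorCovariance(nx = 1e4, nY = 1e4, kxY = 0.5,
#'                       Kxx = diag(1), RxY = matrix(c(1, .4, .4, 1), 2))
#' rhoME(ec)  # off-diagonal = 0.5 * 0.4
#' @export
errorCovariance <- function(nx, nY, kxY, Kxx, RxY) {
  p <- length(nx)
  RxY <- checkCorrelationMatrix(RxY, "RxY")
  if (nrow(RxY) != p + 1L)
    stop("RxY must be (p+1) x (p+1), outcome first", call. = FALSE)
  if (length(kxY) != p) stop("kxY must have length p", call. = FALSE)
  if (!is.matrix(Kxx) || nrow(Kxx) != p || ncol(Kxx) != p)
    stop("Kxx must be p x p", call. = FALSE)
  n <- c(nY, nx)
  K <- matrix(0, p + 1L, p + 1L)
  K[1L, 1L] <- 1
  K[1L, -1L] <- K[-1L, 1L] <- kxY
  K[-1L, -1L] <- Kxx
  if (any(K < 0 | K > 1))
    stop("overlap proportions must lie in [0,1]", call. = FALSE)
  nShared <- K * outer(n, n, pmin)
  bad <- nShared > outer(n, n, pmin) + 1e-9
  if (any(bad))
    stop("implied overlap count exceeds the smaller study's sample size",
         call. = FALSE)
  Omega <- nShared * RxY / outer(n, n)
  diag(Omega) <- 1 / n
  new("ErrorCovariance", p = as.integer(p), Omega = Omega,
      RhoME = stats::cov2cor(Omega))
}

#' Draw per-SNP GWAS estimation errors
#'
#' Draws M independent (p+1)-variate normal rows with covariance `Omega`.
#' The first coordinate of each row is the outcome error `wAlpha`; the
#' remaining p coordinates form the rows of `Wbeta`.
#'
#' @param ec an [ErrorCovariance-class] object.
#' @param M number of SNPs (rows) to draw.
#' @return list with `wAlpha` (M-vector) and `Wbeta` (M x p matrix).
#' @export
drawEstimationErrors <- function(ec, M) {
  stopifnot(is(ec, "ErrorCovariance"))
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be a positive integer", call. = FALSE)
  L <- matSqrt(ec@Omega)
  E <- matrix(stats::rnorm(M * (ec@p + 1L)), M) %*% t(L)
  list(wAlpha = E[, 1L], Wbeta = E[, -1L, drop = FALSE])
}

#' Draw estimated squared standard errors
#'
#' Draws GWAS-estimated squared standard errors for standardized
#' (variance-1) phenotypes and genotypes: `SE^2 = X / (n * (n - 1))` with
#' `X ~ chi-square(n - 1)`, so `E[SE^2] = 1/n` and the coefficient of
#' variation shrinks as `sqrt(2 / (n - 1))`.
#'
#' @param n GWAS sample size (>= 2).
#' @param M number of SNPs.
#' @return M-vector of strictly positive squared standard errors.
#' @export
drawSquaredSE <- function(n, M) {
  if (n < 2) stop("n must be >= 2 to estimate a standard error",
                  call. = FALSE)
  stats::rchisq(M, df = n - 1) / (n * (n - 1))
}

#' Draw a reference-panel-estimated LD matrix
#'
#' Draws `W ~ Wishart(nref, R_S)` and standardizes it to a correlation
#' matrix (the scale convention cancels in the standardization). With
#' `nref = Inf` the true matrix is returned unchanged (exact LD).
#'
#' @param R_S true LD correlation matrix of the selected IVs.
#' @param nref reference-panel size; must exceed `nrow(R_S)` when finite.
#' @return estimated LD correlation matrix of the same dimension.
#' @export
drawEstimatedLD <- function(R_S, nref) {
  nref <- normalizeNref(nref)
  if (is.infinite(nref)) return(R_S)
  d <- nrow(R_S)
  if (nref <= d)
    stop("finite nref (", nref, ") must exceed the number of IVs (", d,
         "); the Wishart draw would be singular", call. = FALSE)
  W <- stats::rWishart(1L, df = nref, Sigma = R_S)[, , 1L]
  stats::cov2cor(W)
}
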