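#' @import methods
NULL

## Central S4 containers. All (p+1)-dimensional objects that mix the outcome
## and the exposures place the outcome in the FIRST row/column.

#' Parameter bundle for the summary-statistic engine
#'
#' Validated parameters for [generateSummary()]. Construct with
#' [summaryParams()] rather than `new()`; the constructor broadcasts scalars
#' to p-vectors, expands covariance-structure expressions such as
#' `"ar1(0.5)"`, and reports every violated constraint at once.
#'
#' @slot p number of exposures.
#' @slot nx p-vector of exposure GWAS sample sizes (individuals).
#' @slot nY outcome GWAS sample size.
#' @slot kxY p-vector of exposure-outcome sample-overlap proportions in [0,1].
#' @slot Kxx p x p matrix of exposure-exposure overlap proportions
#'   (unit diagonal).
#' @slot RxY (p+1) x (p+1) phenotypic correlation matrix, outcome first.
#' @slot h p-vector of SNP heritabilities (each in [0,1]).
#' @slot Rbb p x p genetic correlation matrix between the exposures.
#' @slot M number of causal exposure SNPs.
#' @slot mU,mC numbers of SNPs carrying uncorrelated (UHP) and correlated
#'   (CHP) horizontal pleiotropy; the two groups are disjoint and
#'   `mU + mC <= M`.
#' @slot rhoU,rhoC pleiotropy variance fractions: the variance of the UHP
#'   (resp. CHP) effects relative to the variance of the mediated effects
#'   `B theta`.
#' @slot zetaC CHP sign-correlation control in (-1, 1]; the default -0.5
#'   makes `cor(B theta, gammaC)` negative on the CHP SNPs.
#' @slot theta p-vector of true causal effects.
#' @slot kappa2 LD pruning threshold on squared correlation, in (0,1].
#' @slot simType `"winners_curse"` (select by p-value threshold `tau`) or
#'   `"weak_ivs"` (calibrate the IV set to mean F-statistic `Ftarget`).
#' @slot stdType `"z"` (z-score standardization) or `"none"`.
#' @slot tau IV selection p-value threshold in (0,1].
#' @slot Ftarget target mean F-statistic (> 1) for weak-instrument sets.
#' @slot R M x M true LD correlation matrix between the causal SNPs.
#' @slot s number of independent LD blocks used when `R` was given as a
#'   structure expression.
#' @slot nref LD reference-panel size (finite > |S|, or `Inf` for exact LD).
#' @slot seed integer RNG seed.
#' @export
setClass("SummaryParams",
  representation(
    p = "integer", nx = "numeric", nY = "numeric", kxY = "numeric",
    Kxx = "matrix", RxY = "matrix", h = "numeric", Rbb = "matrix",
    M = "integer", mU = "integer", mC = "integer",
    rhoU = "numeric", rhoC = "numeric", zetaC = "numeric",
    theta = "numeric", kappa2 = "numeric", simType = "character",
    stdType = "character", tau = "numeric", Ftarget = "numeric",
    R = "matrix", s = "integer", nref = "numeric", seed = "integer"
  )
)

#' Parameter bundle for the individual-level engine
#'
#' Validated parameters for [generateIndividual()]. Construct with
#' [individualParams()]. The engine simulates standardized genotypes, a
#' confounder U, p exposures and an outcome from a structural equation
#' model, then runs per-SNP OLS GWAS on (possibly overlapping) exposure and
#' outcome samples.
#'
#' @slot p number of exposures.
#' @slot covXU p x p conditional covariance of the exposures given the
#'   confounder U, `Cov(x | U)`; its unit-scale diagonal entries control how
#'   strongly each exposure is confounded.
#' @slot h p-vector of exposure SNP heritabilities.
#' @slot varYUX p-vector of conditional outcome variances `Var(Y | U, x_k)`,
#'   one per exposure; smaller values mean a stronger causal effect.
#' @slot signTheta p-vector in {-1, +1}: the sign of each causal effect.
#' @slot Rxx optional p x p phenotypic correlation matrix between the
#'   exposures, used as a consistency check against the correlations implied
#'   by `covXU` (0 x 0 matrix when unused).
#' @slot Rbb p x p genetic correlation matrix between the exposures.
#' @slot n1,n0 exposure and outcome GWAS sample sizes. All exposure GWAS
#'   share one sample.
#' @slot p01 exposure-outcome overlap proportion in [0,1]; the two GWAS
#'   share `round(p01 * min(n0, n1))` individuals.
#' @slot M number of causal exposure SNPs.
#' @slot R M x M true LD correlation matrix.
#' @slot nref LD reference-panel size (or `Inf`).
#' @slot mU,mC UHP and CHP SNP counts (disjoint groups, `mU + mC <= M`).
#' @slot sigma2GammaU variance in Y explained by the UHP SNPs, in [0,1).
#' @slot sigma2GammaC variance in U explained by the CHP SNPs, in [0,1).
#' @slot kappa2,simType,stdType,tau,Ftarget IV selection and
#'   standardization controls, as in [summaryParams()].
#' @slot maf minor allele frequency used for the binomial genotype draws.
#' @slot seed integer RNG seed.
#' @export
setClass("IndividualParams",
  representation(
    p = "integer", covXU = "matrix", h = "numeric", varYUX = "numeric",
    signTheta = "numeric", Rxx = "matrix", Rbb = "matrix",
    n1 = "numeric", n0 = "numeric", p01 = "numeric",
    M = "integer", R = "matrix", nref = "numeric",
    mU = "integer", mC = "integer",
    sigma2GammaU = "numeric", sigma2GammaC = "numeric",
    kappa2 = "numeric", simType = "character", stdType = "character",
    tau = "numeric", Ftarget = "numeric", maf = "numeric", seed = "integer"
  )
)

#' Covariance of GWAS estimation errors under sample overlap
#'
#' The (p+1) x (p+1) covariance matrix Omega of the per-SNP GWAS estimation
#' errors on the standardized scale, outcome in the first row/column, and
#' its correlation form RhoME. Overlapping GWAS samples make estimation
#' errors of different studies correlated; with no overlap Omega is
#' diagonal with entries 1/n.
#'
#' @slot p number of exposures.
#' @slot Omega (p+1) x (p+1) error covariance; diagonal `1/nY, 1/nx_1, ...`.
#' @slot RhoME corresponding correlation matrix.
#' @seealso [errorCovariance()]
#' @export
setClass("ErrorCovariance",
  representation(p = "integer", Omega = "matrix", RhoME = "matrix"),
  validity = function(object) {
    msg <- character()
    O <- object@Omega
    if (nrow(O) != object@p + 1L || ncol(O) != object@p + 1L)
      msg <- c(msg, "Omega must be (p+1) x (p+1)")
    if (max(abs(O - t(O))) > 1e-12) msg <- c(msg, "Omega must be symmetric")
    if (any(diag(O) <= 0)) msg <- c(msg, "Omega diagonal must be positive")
    R <- object@RhoME
    if (any(abs(diag(R) - 1) > 1e-8))
      msg <- c(msg, "RhoME must have unit diagonal")
    if (length(msg)) msg else TRUE
  }
)

#' True genetic model underlying a simulated dataset
#'
#' The SNP-level truth generated before estimation noise and instrument
#' selection: true SNP-exposure effects B, pleiotropy effects, true
#' SNP-outcome effects alpha, and per-SNP labels. The identity
#' `alpha = B %*% theta + gammaU + gammaC` holds exactly, so valid SNPs
#' satisfy `alpha_j = b_j' theta`.
#'
#' @slot B M x p true SNP-exposure effects.
#' @slot gammaU M-vector of uncorrelated horizontal pleiotropy effects,
#'   nonzero only on SNPs `1..mU`.
#' @slot gammaC M-vector of correlated horizontal pleiotropy effects,
#'   nonzero only on SNPs `mU+1..mU+mC`.
#' @slot alpha M-vector of true SNP-outcome effects.
#' @slot theta p-vector of causal effects.
#' @slot SigmaBB p x p genetic covariance of the exposures,
#'   `diag(sqrt(h)) %*% Rbb %*% diag(sqrt(h))`.
#' @slot ivType M-vector of labels in {"valid", "UHP", "CHP"}.
#' @export
setClass("TrueEffects",
  representation(
    B = "matrix", gammaU = "numeric", gammaC = "numeric",
    alpha = "numeric", theta = "numeric", SigmaBB = "matrix",
    ivType = "character"
  ),
  validity = function(object) {
    msg <- character()
    M <- nrow(object@B)
    if (length(object@gammaU) != M || length(object@gammaC) != M ||
        length(object@alpha) != M || length(object@ivType) != M)
      msg <- c(msg, "per-SNP slots must all have length nrow(B)")
    if (ncol(object@B) != length(object@theta))
      msg <- c(msg, "ncol(B) must equal length(theta)")
    resid <- object@alpha -
      (as.numeric(object@B %*% object@theta) + object@gammaU + object@gammaC)
    if (length(resid) && max(abs(resid)) > 1e-10)
      msg <- c(msg, "alpha must equal B %*% theta + gammaU + gammaC")
    if (!all(object@ivType %in% c("valid", "UHP", "CHP")))
      msg <- c(msg, "ivType labels must be valid/UHP/CHP")
    if (length(msg)) msg else TRUE
  }
)

#' Solved structural equation model for the individual-level engine
#'
#' Path coefficients and residual scales solved by moment matching so that
#' the confounder U, every exposure and the outcome all have variance 1,
#' `Cov(x | U)` matches the user matrix, and `Var(Y | U, x_k)` matches the
#' user targets. `implied` carries the model-implied covariances used for
#' diagnostics and for the analytic error-correlation matrix.
#'
#' @slot B M x p SNP-exposure path coefficients (columns rescaled so
#'   `diag(B'B) = h` exactly).
#' @slot gammaU,gammaC M-vectors of pleiotropy path coefficients.
#' @slot piX p-vector of confounder-to-exposure effects.
#' @slot piY confounder-to-outcome effect (negative by convention).
#' @slot theta p-vector of causal effects.
#' @slot residSdU,residSdY residual standard deviations of U and Y.
#' @slot SigmaEpsX p x p covariance of the exposure residuals.
#' @slot implied list of model-implied moments (total exposure covariance,
#'   covariances with U and Y, marginal per-SNP associations).
#' @export
setClass("StructuralModel",
  representation(
    B = "matrix", gammaU = "numeric", gammaC = "numeric",
    piX = "numeric", piY = "numeric", theta = "numeric",
    residSdU = "numeric", residSdY = "numeric", SigmaEpsX = "matrix",
    implied = "list"
  )
)

#' Simulated individual-level phenotypes
#'
#' @slot x n x p exposure matrix.
#' @slot Y n-vector outcome.
#' @slot U n-vector confounder.
#' @export
setClass("PhenotypeSet",
  representation(x = "matrix", Y = "numeric", U = "numeric")
)

#' Simulated MR summary dataset
#'
#' The complete output bundle of either engine: standardized and
#' unstandardized SNP association estimates and standard errors for the
#' selected instruments, their true and reference-panel-estimated LD
#' matrices, per-IV labels, the true causal effects, and the correlation
#' matrix of GWAS estimation errors. Use the accessors ([bx()], [by()],
#' [bxse()], [byse()], [ivType()], [ldMatrix()], [ldHatMatrix()],
#' [rhoME()], [causalEffects()], [ivIndex()], [trueEffects()]) rather than
#' slots.
#'
#' @slot ivIndex integer indices (into 1..M) of the selected IV set S.
#' @slot bx,bxse |S| x p standardized SNP-exposure estimates and SEs.
#' @slot by,byse |S|-vectors of standardized SNP-outcome estimates and SEs.
#' @slot bxUnstd,bxseUnstd,byUnstd,byseUnstd unstandardized counterparts.
#' @slot ivType |S|-vector of labels in {"valid", "UHP", "CHP"}.
#' @slot theta p-vector of true causal effects.
#' @slot rhoME (p+1) x (p+1) error-correlation matrix, outcome first.
#' @slot ldMatrix,ldHatMatrix |S| x |S| true and estimated LD matrices
#'   (identical when `nref = Inf`).
#' @slot truth the [TrueEffects-class] object for all M SNPs (or `NULL`
#'   when read back from disk).
#' @slot params the generating parameter object (or `NULL`).
#' @slot meta list: engine, seed, per-exposure mean F-statistics, IV-type
#'   counts.
#' @export
setClass("MRDataset",
  representation(
    ivIndex = "integer",
    bx = "matrix", bxse = "matrix", by = "numeric", byse = "numeric",
    bxUnstd = "matrix", bxseUnstd = "matrix",
    byUnstd = "numeric", byseUnstd = "numeric",
    ivType = "character", theta = "numeric", rhoME = "matrix",
    ldMatrix = "matrix", ldHatMatrix = "matrix",
    truth = "ANY", params = "ANY", meta = "list"
  ),
  validity = function(object) {
    msg <- character()
    nS <- length(object@ivIndex)
    if (nS < 1L) msg <- c(msg, "the IV set must contain at least one SNP")
    lens <- c(nrow(object@bx), nrow(object@bxse), length(object@by),
              length(object@byse), nrow(object@bxUnstd),
              nrow(object@bxseUnstd), length(object@byUnstd),
              length(object@byseUnstd), length(object@ivType),
              nrow(object@ldMatrix), nrow(object@ldHatMatrix))
    if (any(lens != nS))
      msg <- c(msg, "all per-IV slots must share length(ivIndex)")
    if (any(abs(diag(object@rhoME) - 1) > 1e-8))
      msg <- c(msg, "rhoME must have unit diagonal")
    if (nrow(object@rhoME) != length(object@theta) + 1L)
      msg <- c(msg, "rhoME must be (p+1) x (p+1), outcome first")
    if (!all(object@ivType %in% c("valid", "UHP", "CHP")))
      msg <- c(msg, "ivType labels must be valid/UHP/CHP")
    if (length(msg)) msg else TRUE
  }
)
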