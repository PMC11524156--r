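## Parameter constructors and validation. Both constructors collect every
## violated constraint and report them in a single error.

normalizeNref <- function(nref) {
  if (is.character(nref)) {
    if (tolower(nref) %in% c("inf", "infinity")) return(Inf)
    nref <- suppressWarnings(as.numeric(nref))
  }
  nref
}

## accept matrix | list-of-rows (from YAML/JSON) | scalar broadcast |
## structure expression
normalizeMatrix <- function(x, dim, what, offDiagScalar = TRUE) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) return(parseCovStructure(x, dim))
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  if (is.matrix(x)) {
    if (nrow(x) != dim || ncol(x) != dim)
      stop(what, " must be ", dim, " x ", dim, ", got ",
           nrow(x), " x ", ncol(x), call. = FALSE)
    return(x)
  }
  if (length(x) == 1L && offDiagScalar) {
    m <- matrix(as.numeric(x), dim, dim)
    diag(m) <- 1
    return(m)
  }
  stop(what, " must be a matrix, a structure expression, or a scalar ",
       "off-diagonal value", call. = FALSE)
}

broadcast <- function(x, p, what) {
  x <- as.numeric(x)
  if (length(x) == 1L) rep(x, p)
  else if (length(x) == p) x
  else stop(what, " must have length 1 or p = ", p, ", got length ",
            length(x), call. = FALSE)
}

#' Construct and validate summary-engine parameters
#'
#' Builds a [SummaryParams-class] bundle for [generateSummary()]. Scalars
#' broadcast to p-vectors; correlation/overlap matrices may be given as
#' numeric matrices, as scalar off-diagonal values, or as structure
#' expressions (see [parseCovStructure()]). The number of exposures is
#' taken from `p` or, if omitted, from `length(theta)`. All violated
#' constraints are reported together in one error.
#'
#' @param theta true causal effect(s); length defines p when `p` is missing.
#' @param M number of causal exposure SNPs.
#' @param p number of exposures.
#' @param nx exposure GWAS sample size(s).
#' @param nY outcome GWAS sample size.
#' @param kxY exposure-outcome overlap proportion(s) in [0,1].
#' @param Kxx exposure-exposure overlap proportions (unit diagonal).
#' @param RxY (p+1) x (p+1) phenotypic correlation matrix, outcome first,
#'   or a scalar off-diagonal correlation.
#' @param h SNP heritability of each exposure, in [0,1].
#' @param Rbb genetic correlation matrix between the exposures.
#' @param mU,mC counts of UHP and CHP SNPs (`mU + mC <= M`).
#' @param rhoU,rhoC pleiotropy variance fractions (>= 0), relative to
#'   `Var(B theta)`.
#' @param zetaC CHP sign-correlation control in (-1, 1].
#' @param kappa2 LD pruning threshold on r^2, in (0,1].
#' @param simType `"winners_curse"` or `"weak_ivs"`.
#' @param stdType `"z"` or `"none"`.
#' @param tau IV p-value threshold in (0,1].
#' @param Ftarget target mean F-statistic (> 1) for `simType = "weak_ivs"`.
#' @param R LD structure between the M causal SNPs: structure expression
#'   (expanded per block, see [buildBlockLD()]) or an M x M matrix.
#' @param s number of independent LD blocks.
#' @param nref LD reference-panel size; `Inf` (or `"Inf"`/`"infinity"`)
#'   skips LD estimation noise.
#' @param seed integer RNG seed.
#' @return a validated [SummaryParams-class] object.
#' @examples
#' summaryParams(theta = c(0.2, -0.1), M = 100, h = 0.3, nx = 5e4, nY = 5e4)
#' @export
summaryParams <- function(theta, M, p = length(theta),
                          nx = 1e5, nY = 1e5, kxY = 0, Kxx = NULL,
                          RxY = 0.3, h = 0.3, Rbb = NULL,
                          mU = 0L, mC = 0L, rhoU = 0, rhoC = 0,
                          zetaC = -0.5, kappa2 = 1,
                          simType = c("winners_curse", "weak_ivs"),
                          stdType = c("z", "none"),
                          tau = 1, Ftarget = 10,
                          R = "I", s = 1L, nref = Inf, seed = 1L) {
  simType <- match.arg(simType)
  stdType <- match.arg(stdType)
  p <- as.integer(p); M <- as.integer(M)
  mU <- as.integer(mU); mC <- as.integer(mC); s <- as.integer(s)
  nref <- normalizeNref(nref)
  bad <- character()
  if (is.na(p) || p < 1L) stop("p must be a positive integer", call. = FALSE)
  if (is.na(M) || M < 1L) stop("M must be a positive integer", call. = FALSE)

  theta <- broadcast(theta, p, "theta")
  nx <- broadcast(nx, p, "nx")
  kxY <- broadcast(kxY, p, "kxY")
  h <- broadcast(h, p, "h")
  Kxx <- if (is.null(Kxx)) diag(p) else normalizeMatrix(Kxx, p, "Kxx")
  RxY <- normalizeMatrix(RxY, p + 1L, "RxY")
  Rbb <- if (is.null(Rbb)) diag(p) else normalizeMatrix(Rbb, p, "Rbb")
  if (is.list(R)) R <- do.call(rbind, lapply(R, as.numeric))
  R <- buildBlockLD(R, M, s)

  if (any(nx < 2) || nY < 2) bad <- c(bad, "sample sizes must be >= 2")
  if (any(kxY < 0 | kxY > 1)) bad <- c(bad, "kxY entries must lie in [0,1]")
  if (any(Kxx < 0 | Kxx > 1)) bad <- c(bad, "Kxx entries must lie in [0,1]")
  if (any(abs(diag(Kxx) - 1) > 1e-12))
    bad <- c(bad, "Kxx diagonal must be 1 (self-overlap is complete)")
  if (max(abs(Kxx - t(Kxx))) > 1e-8) bad <- c(bad, "Kxx must be symmetric")
  if (any(h < 0 | h > 1)) bad <- c(bad, "heritabilities h must lie in [0,1]")
  if (mU < 0L || mC < 0L) bad <- c(bad, "mU and mC must be nonnegative")
  if (mU + mC > M) bad <- c(bad, "mU + mC exceeds M")
  if (rhoU < 0 || rhoC < 0) bad <- c(bad, "rhoU and rhoC must be >= 0")
  if (zetaC <= -1 || zetaC > 1) bad <- c(bad, "zetaC must lie in (-1, 1]")
  if (kappa2 <= 0 || kappa2 > 1) bad <- c(bad, "kappa2 must lie in (0,1]")
  if (tau <= 0 || tau > 1) bad <- c(bad, "tau must lie in (0,1]")
  if (Ftarget <= 1) bad <- c(bad, "Ftarget must exceed 1")
  if (is.na(nref) || nref <= 0) bad <- c(bad, "nref must be positive or Inf")
  err <- tryCatch({
    checkCorrelationMatrix(RxY, "RxY")
    checkCorrelationMatrix(Rbb, "Rbb")
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(err)) bad <- c(bad, err)
  if (length(bad))
    stop("invalid summary parameters:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)

  new("SummaryParams", p = p, nx = nx, nY = as.numeric(nY), kxY = kxY,
      Kxx = Kxx, RxY = RxY, h = h, Rbb = Rbb, M = M, mU = mU, mC = mC,
      rhoU = as.numeric(rhoU), rhoC = as.numeric(rhoC),
      zetaC = as.numeric(zetaC), theta = theta,
      kappa2 = as.numeric(kappa2), simType = simType, stdType = stdType,
      tau = as.numeric(tau), Ftarget = as.numeric(Ftarget), R = R, s = s,
      nref = nref, seed = as.integer(seed))
}

#' Construct and validate individual-engine parameters
#'
#' Builds an [IndividualParams-class] bundle for [generateIndividual()].
#' Scalars broadcast to p-vectors and matrices may be given as structure
#' expressions. Residual-variance feasibility (whether the requested
#' heritabilities, pleiotropy shares, confounding and conditional outcome
#' variances leave every node a nonnegative residual variance) is checked
#' when the structural model is solved.
#'
#' @param M number of causal exposure SNPs.
#' @param p number of exposures.
#' @param covXU p x p conditional covariance `Cov(x | U)` of the exposures
#'   given the confounder (diagonal entries in (0, 1]; `1 - covXU[k,k]` is
#'   exposure k's confounded variance share). Scalar input fills the
#'   off-diagonal.
#' @param h exposure SNP heritabilities in [0,1].
#' @param varYUX conditional outcome variances `Var(Y | U, x_k)`, one per
#'   exposure; with no confounding `varYUX = 1 - theta^2`.
#' @param signTheta sign (+1/-1) of each causal effect.
#' @param Rxx optional phenotypic correlation matrix between exposures,
#'   checked for consistency with `covXU` (warning on conflict).
#' @param Rbb genetic correlation matrix between exposures.
#' @param n1,n0 exposure and outcome GWAS sample sizes.
#' @param p01 exposure-outcome overlap proportion in [0,1].
#' @param R LD structure (expression or M x M matrix).
#' @param nref LD reference-panel size (or `Inf`).
#' @param mU,mC UHP / CHP SNP counts.
#' @param sigma2GammaU variance in Y explained by UHP SNPs, in [0,1).
#' @param sigma2GammaC variance in U explained by CHP SNPs, in [0,1).
#' @param kappa2,simType,stdType,tau,Ftarget IV selection controls as in
#'   [summaryParams()].
#' @param maf allele frequency for the binomial genotype draws, in (0, 0.5].
#' @param seed integer RNG seed.
#' @return a validated [IndividualParams-class] object.
#' @examples
#' individualParams(M = 50, p = 1, varYUX = 0.96, n1 = 2e4, n0 = 2e4)
#' @export
individualParams <- function(M, p = 1L, covXU = NULL, h = 0.3,
                             varYUX = 0.96, signTheta = 1, Rxx = NULL,
                             Rbb = NULL, n1 = 1e5, n0 = 1e5, p01 = 0,
                             R = "I", nref = Inf, mU = 0L, mC = 0L,
                             sigma2GammaU = 0, sigma2GammaC = 0,
                             kappa2 = 1,
                             simType = c("winners_curse", "weak_ivs"),
                             stdType = c("z", "none"),
                             tau = 1, Ftarget = 10, maf = 0.3, seed = 1L) {
  simType <- match.arg(simType)
  stdType <- match.arg(stdType)
  p <- as.integer(p); M <- as.integer(M)
  mU <- as.integer(mU); mC <- as.integer(mC)
  nref <- normalizeNref(nref)
  if (is.na(p) || p < 1L) stop("p must be a positive integer", call. = FALSE)
  if (is.na(M) || M < 1L) stop("M must be a positive integer", call. = FALSE)
  bad <- character()

  h <- broadcast(h, p, "h")
  varYUX <- broadcast(varYUX, p, "varYUX")
  signTheta <- broadcast(signTheta, p, "signTheta")
  covXU <- if (is.null(covXU)) diag(p)
           else normalizeMatrix(covXU, p, "covXU")
  if (is.null(covXU)) covXU <- diag(p)
  Rbb <- if (is.null(Rbb)) diag(p) else normalizeMatrix(Rbb, p, "Rbb")
  Rxx <- if (is.null(Rxx)) matrix(numeric(0), 0, 0)
         else normalizeMatrix(Rxx, p, "Rxx")
  if (is.list(R)) R <- do.call(rbind, lapply(R, as.numeric))
  R <- if (is.matrix(R)) checkCorrelationMatrix(R, "LD matrix R")
       else parseCovStructure(R, M)
  if (is.matrix(R) && nrow(R) != M)
    bad <- c(bad, "LD matrix R must be M x M")

  if (n1 < 3 || n0 < 3) bad <- c(bad, "n1 and n0 must be >= 3")
  if (p01 < 0 || p01 > 1) bad <- c(bad, "p01 must lie in [0,1]")
  if (any(h < 0 | h > 1)) bad <- c(bad, "heritabilities h must lie in [0,1]")
  if (any(varYUX <= 0 | varYUX > 1))
    bad <- c(bad, "varYUX entries must lie in (0, 1]")
  if (!all(signTheta %in% c(-1, 1)))
    bad <- c(bad, "signTheta entries must be -1 or +1")
  if (any(diag(covXU) <= 0 | diag(covXU) > 1))
    bad <- c(bad, "diag(covXU) entries must lie in (0, 1]")
  if (mU < 0L || mC < 0L) bad <- c(bad, "mU and mC must be nonnegative")
  if (mU + mC > M) bad <- c(bad, "mU + mC exceeds M")
  if (sigma2GammaU < 0 || sigma2GammaU >= 1)
    bad <- c(bad, "sigma2GammaU must lie in [0, 1)")
  if (sigma2GammaC < 0 || sigma2GammaC >= 1)
    bad <- c(bad, "sigma2GammaC must lie in [0, 1)")
  if (kappa2 <= 0 || kappa2 > 1) bad <- c(bad, "kappa2 must lie in (0,1]")
  if (tau <= 0 || tau > 1) bad <- c(bad, "tau must lie in (0,1]")
  if (Ftarget <= 1) bad <- c(bad, "Ftarget must exceed 1")
  if (maf <= 0 || maf > 0.5) bad <- c(bad, "maf must lie in (0, 0.5]")
  if (is.na(nref) || nref <= 0) bad <- c(bad, "nref must be positive or Inf")
  if (length(bad))
    stop("invalid individual parameters:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)

  new("IndividualParams", p = p, covXU = covXU, h = h, varYUX = varYUX,
      signTheta = signTheta, Rxx = Rxx, Rbb = Rbb,
      n1 = as.numeric(n1), n0 = as.numeric(n0), p01 = as.numeric(p01),
      M = M, R = R, nref = nref, mU = mU, mC = mC,
      sigma2GammaU = as.numeric(sigma2GammaU),
      sigma2GammaC = as.numeric(sigma2GammaC),
      kappa2 = as.numeric(kappa2), simType = simType, stdType = stdType,
      tau = as.numeric(tau), Ftarget = as.numeric(Ftarget),
      maf = as.numeric(maf), seed = as.integer(seed))
}

#' Load parameters from a configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration whose keys
#' match the arguments of [summaryParams()] or [individualParams()], plus an
#' `engine` key (`"summary"` or `"individual"`, default `"summary"`).
#' Matrices may be written as nested lists of rows or as structure
#' expressions. Unknown keys produce a warning naming them.
#'
#' @param path path to the configuration file.
#' @return a [SummaryParams-class] or [IndividualParams-class] object.
#' @export
loadParams <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must parse to a named list", call. = FALSE)
  paramsFromList(raw)
}

#' @rdname loadParams
#' @param raw a named list of parameters (as parsed from a config file).
#' @export
paramsFromList <- function(raw) {
  engine <- tolower(raw$engine %||% "summary")
  raw$engine <- NULL
  ctor <- switch(engine,
                 summary = summaryParams,
                 individual = individualParams,
                 stop("unknown engine '", engine,
                      "' (expected \"summary\" or \"individual\")",
                      call. = FALSE))
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown parameter key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(ctor, raw[intersect(names(raw), known)])
}

#' Convert a parameter object to a plain named list
#'
#' Inverse of [paramsFromList()]: the returned list (matrices as nested
#' row lists) regenerates an identical parameter object, and is what
#' [writeDataset()] stores in the run metadata.
#'
#' @param params a [SummaryParams-class] or [IndividualParams-class] object.
#' @return a named list including an `engine` key.
#' @export
paramsAsList <- function(params) {
  engine <- if (is(params, "SummaryParams")) "summary" else "individual"
  nm <- slotNames(class(params))
  out <- lapply(nm, function(s) {
    v <- slot(params, s)
    if (is.matrix(v)) {
      if (length(v) == 0L) NULL
      else lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
    } else if (is.numeric(v) && any(is.infinite(v))) "Inf"
    else v
  })
  names(out) <- nm
  out <- out[!vapply(out, is.null, logical(1))]
  ## R is serialized as the fully expanded block matrix, so the block count
  ## must reset to 1 on reload
  if (engine == "summary") out$s <- 1L
  c(list(engine = engine), out)
}
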