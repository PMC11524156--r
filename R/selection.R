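## Instrument selection (LD pruning, winner's-curse thresholding, mean-F
## targeting), z-score standardization, and assembly of the MRDataset.

#' Two-sided Wald p-values
#'
#' @param bhat estimate vector (or matrix).
#' @param se matching standard errors (all > 0).
#' @return p-values `2 * (1 - Phi(|bhat / se|))`, same shape as `bhat`.
#' @export
waldPvalues <- function(bhat, se) {
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  2 * stats::pnorm(-abs(bhat / se))
}

#' Greedy LD pruning
#'
#' Visits SNPs in priority order (smallest `priority` value first, ties
#' broken by lower index) and keeps a SNP iff its squared correlation with
#' every already-kept SNP is at most `kappa2`. The returned set therefore
#' contains no pair with `r^2 > kappa2`.
#'
#' @param R LD correlation matrix.
#' @param priority numeric vector (length `nrow(R)`); smaller = kept first.
#'   Typically the per-SNP minimum p-value, matching GWAS clumping.
#' @param kappa2 squared-correlation threshold in (0, 1].
#' @return sorted integer vector of kept indices.
#' @export
ldPrune <- function(R, priority, kappa2) {
  m <- nrow(R)
  if (length(priority) != m)
    stop("priority must have length nrow(R)", call. = FALSE)
  if (kappa2 <= 0 || kappa2 > 1)
    stop("kappa2 must lie in (0, 1]", call. = FALSE)
  if (kappa2 == 1) return(seq_len(m))
  ord <- order(priority, seq_len(m))
  kept <- integer(0)
  R2 <- R * R
  for (j in ord) {
    if (!length(kept) || all(R2[j, kept] <= kappa2)) kept <- c(kept, j)
  }
  sort(kept)
}

#' Select instruments by p-value threshold and LD pruning
#'
#' Winner's-curse selection: a SNP is a candidate iff its minimum Wald
#' p-value across exposures is below `tau` (for one exposure, its own
#' p-value); candidates are then LD-pruned at `kappa2` with priority given
#' to the most significant SNPs. This is the union of the
#' exposure-specific instrument sets, the multivariable-MR convention.
#'
#' @param pvals M x p matrix (or M-vector) of exposure-association
#'   p-values.
#' @param tau p-value threshold in (0, 1]; `tau = 1` keeps every SNP.
#' @param R M x M LD correlation matrix.
#' @param kappa2 LD pruning threshold.
#' @return sorted integer vector of selected indices.
#' @export
selectIVs <- function(pvals, tau, R, kappa2) {
  pm <- as.matrix(pvals)
  minp <- do.call(pmin, c(lapply(seq_len(ncol(pm)), function(k) pm[, k]),
                          list(na.rm = FALSE)))
  cand <- if (tau >= 1) seq_len(nrow(pm)) else which(minp < tau)
  if (!length(cand))
    stop(structure(
      list(message = paste0(
        "no SNP passed the IV p-value threshold tau = ", tau,
        "; relax tau (or increase sample size / heritability)"),
        call = NULL),
      class = c("MRsimSelectionError", "error", "condition")))
  kept <- ldPrune(R[cand, cand, drop = FALSE], minp[cand], kappa2)
  sort(cand[kept])
}

#' Per-exposure mean F-statistic
#'
#' Mean over the selected SNPs of the squared z-statistics
#' `(bhat / se)^2`, one value per exposure. Invariant to z-score
#' standardization.
#'
#' @param bhat |S| x p estimate matrix (or vector).
#' @param se matching standard errors.
#' @return p-vector of mean F-statistics.
#' @export
meanFStatistic <- function(bhat, se) {
  z2 <- (as.matrix(bhat) / as.matrix(se))^2
  colMeans(z2)
}

#' Calibrate an IV set to a target mean F-statistic
#'
#' Weak-instrument calibration: iteratively removes the SNP with the
#' largest per-SNP F (averaged across exposures) while the mean F exceeds
#' the target, then returns the step whose achieved mean F is closest to
#' the target. Removing the largest F strictly decreases the mean, so the
#' trajectory is monotone. If the initial mean F is already at or below
#' the target, the full set is returned with a warning (exclusion cannot
#' raise F).
#'
#' @param bhat |S| x p estimate matrix (or vector).
#' @param se matching standard errors.
#' @param Ftarget target mean F-statistic (> 1).
#' @return list with `keep` (surviving indices into the rows of `bhat`),
#'   `achieved` (mean F of the returned set) and `trajectory` (mean F after
#'   each considered removal, starting with the full set).
#' @export
targetFStatistic <- function(bhat, se, Ftarget) {
  if (Ftarget <= 1) stop("Ftarget must exceed 1", call. = FALSE)
  f <- rowMeans((as.matrix(bhat) / as.matrix(se))^2)
  m <- length(f)
  meanF0 <- mean(f)
  if (meanF0 <= Ftarget) {
    warning("mean F (", signif(meanF0, 4), ") is already <= the target (",
            Ftarget, "); returning the full set", call. = FALSE)
    return(list(keep = seq_len(m), achieved = meanF0, trajectory = meanF0))
  }
  ord <- order(f, decreasing = TRUE)       # removal order (static F values)
  total <- sum(f)
  ## mean F after removing the t largest, t = 0 .. m-1
  traj <- (total - cumsum(c(0, f[ord[-m]]))) / (m - 0:(m - 1L))
  ## walk until the mean first drops to/below the target, then pick the
  ## step closest to it
  cross <- which(traj <= Ftarget)
  tMax <- if (length(cross)) cross[1L] - 1L else m - 1L
  cand <- 0:tMax
  best <- cand[which.min(abs(traj[cand + 1L] - Ftarget))]
  keep <- if (best == 0L) seq_len(m) else sort(setdiff(seq_len(m),
                                                       ord[seq_len(best)]))
  list(keep = keep, achieved = mean(f[keep]),
       trajectory = traj[seq_len(tMax + 1L)])
}

#' Standardize GWAS estimates
#'
#' `mode = "none"` returns the input unchanged. `mode = "z"` applies
#' z-score standardization: `b = (bhat / se) / sqrt(n)`, `se = 1 / sqrt(n)`,
#' which preserves every z-statistic exactly.
#'
#' @param bhat estimates (vector or matrix).
#' @param se matching standard errors.
#' @param n GWAS sample size (scalar, or one per column of a matrix).
#' @param mode `"z"` or `"none"`.
#' @return list with `b` and `se` in the same shape as the input.
#' @export
standardizeEstimates <- function(bhat, se, n, mode = c("z", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(list(b = bhat, se = se))
  if (is.matrix(bhat)) {
    n <- if (length(n) == 1L) rep(n, ncol(bhat)) else n
    b <- sweep(bhat / se, 2L, sqrt(n), "/")
    s <- matrix(rep(1 / sqrt(n), each = nrow(bhat)), nrow(bhat))
    list(b = b, se = s)
  } else {
    list(b = (bhat / se) / sqrt(n), se = rep(1 / sqrt(n), length(bhat)))
  }
}

## Shared final stage of both engines: IV selection, standardization,
## Wishart LD, and MRDataset construction.
assembleDataset <- function(Bhat, bxse, alphaHat, byse, truth, ec, R, nref,
                            simType, stdType, tau, kappa2, Ftarget,
                            nx, nY, params, engine, seed,
                            rhoMEOverride = NULL) {
  M <- nrow(Bhat)
  pv <- waldPvalues(Bhat, bxse)
  S <- selectIVs(pv, if (simType == "winners_curse") tau else 1,
                 R, kappa2)
  fInfo <- NULL
  if (simType == "weak_ivs") {
    fInfo <- targetFStatistic(Bhat[S, , drop = FALSE],
                              bxse[S, , drop = FALSE], Ftarget)
    S <- S[fInfo$keep]
  }
  if (!length(S))
    stop("IV selection produced an empty set; relax tau/kappa2",
         call. = FALSE)

  bxU <- Bhat[S, , drop = FALSE]
  bxseU <- bxse[S, , drop = FALSE]
  byU <- alphaHat[S]
  byseU <- byse[S]
  sx <- standardizeEstimates(bxU, bxseU, nx, stdType)
  sy <- standardizeEstimates(byU, byseU, nY, stdType)

  RS <- R[S, S, drop = FALSE]
  RShat <- withSubstream(seed, "wishart-ld", drawEstimatedLD(RS, nref))

  rhoME <- if (is.null(rhoMEOverride)) ec@RhoME else rhoMEOverride
  meanF <- meanFStatistic(sx$b, sx$se)
  new("MRDataset",
      ivIndex = as.integer(S),
      bx = as.matrix(sx$b), bxse = as.matrix(sx$se),
      by = as.numeric(sy$b), byse = as.numeric(sy$se),
      bxUnstd = as.matrix(bxU), bxseUnstd = as.matrix(bxseU),
      byUnstd = as.numeric(byU), byseUnstd = as.numeric(byseU),
      ivType = truth@ivType[S], theta = truth@theta, rhoME = rhoME,
      ldMatrix = RS, ldHatMatrix = RShat,
      truth = truth, params = params,
      meta = list(engine = engine, seed = seed, nref = nref,
                  meanF = meanF,
                  ivCounts = table(factor(truth@ivType[S],
                                          levels = c("valid", "UHP",
                                                     "CHP"))),
                  achievedF = if (is.null(fInfo)) NULL else fInfo$achieved))
}
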