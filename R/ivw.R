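## Inverse-variance-weighted estimator. Included as the package's built-in
## reference estimator for checking that simulated datasets recover the
## generating causal effects; it is deliberately the plainest fixed-effect
## IVW (no intercept, weights 1/byse^2), not a featured MR method.

ivwFit <- function(bx, by, byse) {
  X <- as.matrix(bx)
  if (length(by) <= ncol(X))
    stop("IVW needs more instruments than exposures", call. = FALSE)
  w <- 1 / byse^2
  XtW <- t(X * w)
  A <- XtW %*% X
  if (rcond(A) < 1e-12)
    stop("singular weighted design in IVW (collinear exposures?)",
         call. = FALSE)
  Ainv <- solve(A)
  thetaHat <- as.numeric(Ainv %*% (XtW %*% by))
  list(thetaHat = thetaHat, se = sqrt(diag(Ainv)))
}

#' @describeIn ivwEstimate IVW on an [MRDataset-class], optionally on a
#'   subset of its instruments (e.g. `which(ivType(ds) == "valid")`).
#' @param subset integer indices into the IV set (default: all IVs).
#' @return list with `thetaHat` (p-vector) and `se` (fixed-effect
#'   standard errors).
#' @examples
#' ds <- generateSummary(summaryParams(theta = 0.2, M = 100, seed = 11))
#' ivwEstimate(ds)$thetaHat
#' @export
setMethod("ivwEstimate", "MRDataset", function(object,
                                               subset = seq_len(nIV(object)),
                                               ...) {
  ivwFit(object@bx[subset, , drop = FALSE], object@by[subset],
         object@byse[subset])
})

#' @describeIn ivwEstimate IVW on raw matrices/vectors.
#' @param by,byse SNP-outcome estimates and standard errors.
#' @export
setMethod("ivwEstimate", "matrix", function(object, by, byse, ...) {
  ivwFit(object, by, byse)
})

#' @describeIn ivwEstimate univariable IVW on plain vectors.
#' @export
setMethod("ivwEstimate", "numeric", function(object, by, byse, ...) {
  ivwFit(matrix(object, ncol = 1L), by, byse)
})
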