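## Accessor generics for the S4 containers. `by` wraps the base function as
## the implicit default method, so base::by(data, INDICES, FUN) still works.

#' @rdname MRDataset-accessors
#' @export
setGeneric("bx", function(object) standardGeneric("bx"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("bxse", function(object) standardGeneric("bxse"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("by", function(data, ...) standardGeneric("by"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("byse", function(object) standardGeneric("byse"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("ivIndex", function(object) standardGeneric("ivIndex"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("ivType", function(object) standardGeneric("ivType"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("causalEffects", function(object) standardGeneric("causalEffects"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("rhoME", function(object) standardGeneric("rhoME"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("ldMatrix", function(object) standardGeneric("ldMatrix"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("ldHatMatrix", function(object) standardGeneric("ldHatMatrix"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("trueEffects", function(object) standardGeneric("trueEffects"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("nIV", function(object) standardGeneric("nIV"))
#' @rdname MRDataset-accessors
#' @export
setGeneric("nExposures", function(object) standardGeneric("nExposures"))

#' Inverse-variance-weighted MR estimate
#'
#' @param object an [MRDataset-class] (or a matrix of SNP-exposure
#'   estimates).
#' @param ... passed to methods.
#' @export
setGeneric("ivwEstimate", function(object, ...) standardGeneric("ivwEstimate"))

#' Accessors for MRDataset objects
#'
#' `bx()`/`bxse()` return the |S| x p standardized SNP-exposure estimates
#' and standard errors; `by()`/`byse()` the SNP-outcome counterparts;
#' `ivIndex()` the selected SNP indices; `ivType()` the per-IV labels;
#' `causalEffects()` the true causal effect vector theta; `rhoME()` the
#' estimation-error correlation matrix (outcome first); `ldMatrix()` and
#' `ldHatMatrix()` the true and reference-panel-estimated LD matrices;
#' `trueEffects()` the full pre-selection [TrueEffects-class] truth;
#' `nIV()` and `nExposures()` the set size |S| and number of exposures.
#'
#' @param object,data an [MRDataset-class] object.
#' @param ... unused (present for compatibility with `base::by`).
#' @return See the description per accessor.
#' @name MRDataset-accessors
#' @examples
#' ds <- generateSummary(summaryParams(theta = 0.2, M = 50, seed = 7))
#' dim(bx(ds)); length(by(ds)); table(ivType(ds))
NULL

#' @rdname MRDataset-accessors
#' @export
setMethod("bx", "MRDataset", function(object) object@bx)
#' @rdname MRDataset-accessors
#' @export
setMethod("bxse", "MRDataset", function(object) object@bxse)
#' @rdname MRDataset-accessors
#' @export
setMethod("by", "MRDataset", function(data, ...) data@by)
#' @rdname MRDataset-accessors
#' @export
setMethod("byse", "MRDataset", function(object) object@byse)
#' @rdname MRDataset-accessors
#' @export
setMethod("ivIndex", "MRDataset", function(object) object@ivIndex)
#' @rdname MRDataset-accessors
#' @export
setMethod("ivType", "MRDataset", function(object) object@ivType)
#' @rdname MRDataset-accessors
#' @export
setMethod("causalEffects", "MRDataset", function(object) object@theta)
#' @rdname MRDataset-accessors
#' @export
setMethod("rhoME", "MRDataset", function(object) object@rhoME)
#' @rdname MRDataset-accessors
#' @export
setMethod("rhoME", "ErrorCovariance", function(object) object@RhoME)
#' @rdname MRDataset-accessors
#' @export
setMethod("ldMatrix", "MRDataset", function(object) object@ldMatrix)
#' @rdname MRDataset-accessors
#' @export
setMethod("ldHatMatrix", "MRDataset", function(object) object@ldHatMatrix)
#' @rdname MRDataset-accessors
#' @export
setMethod("trueEffects", "MRDataset", function(object) object@truth)
#' @rdname MRDataset-accessors
#' @export
setMethod("nIV", "MRDataset", function(object) length(object@ivIndex))
#' @rdname MRDataset-accessors
#' @export
setMethod("nExposures", "MRDataset", function(object) length(object@theta))
#' @rdname MRDataset-accessors
#' @export
setMethod("nExposures", "SummaryParams", function(object) object@p)
#' @rdname MRDataset-accessors
#' @export
setMethod("nExposures", "IndividualParams", function(object) object@p)

#' @export
setMethod("show", "MRDataset", function(object) {
  p <- length(object@theta)
  cat(sprintf("MRDataset (%s engine): %d IVs, %d exposure%s\n",
              object@meta$engine %||% "?", length(object@ivIndex), p,
              if (p == 1L) "" else "s"))
  tab <- table(factor(object@ivType, levels = c("valid", "UHP", "CHP")))
  cat("  IV types: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  theta:    ", paste(signif(object@theta, 3), collapse = ", "), "\n")
  if (!is.null(object@meta$meanF))
    cat("  mean F:   ", paste(signif(object@meta$meanF, 4), collapse = ", "),
        "\n")
  cat("  LD:        nref =",
      if (isTRUE(is.infinite(object@meta$nref))) "Inf (exact)"
      else format(object@meta$nref), "\n")
  invisible(object)
})

#' @export
setMethod("show", "SummaryParams", function(object) {
  cat(sprintf(
    "SummaryParams: p=%d, M=%d (UHP %d, CHP %d), nY=%g, sim=%s, std=%s\n",
    object@p, object@M, object@mU, object@mC, object@nY, object@simType,
    object@stdType))
  invisible(object)
})

#' @export
setMethod("show", "IndividualParams", function(object) {
  cat(sprintf(
    "IndividualParams: p=%d, M=%d (UHP %d, CHP %d), n1=%g, n0=%g, p01=%g\n",
    object@p, object@M, object@mU, object@mC, object@n1, object@n0,
    object@p01))
  invisible(object)
})

#' @export
setMethod("show", "ErrorCovariance", function(object) {
  cat(sprintf("ErrorCovariance for %d exposure(s), outcome first\n",
              object@p))
  cat("RhoME:\n")
  print(signif(object@RhoME, 4))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
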