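## Correlation-structure mini-language: "ar1(a)", "toeplitz", "I", plus
## block-diagonal assembly for LD matrices.

#' Validate a correlation matrix
#'
#' Checks symmetry, unit diagonal, off-diagonal entries in [-1, 1], and
#' positive semi-definiteness (smallest eigenvalue >= -1e-8). Returns the
#' symmetrized matrix invisibly so callers can normalize tiny asymmetries.
#'
#' @param m numeric square matrix.
#' @param what label used in error messages.
#' @return the validated (symmetrized) matrix, invisibly.
#' @export
checkCorrelationMatrix <- function(m, what = "correlation matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(what, " must be a square numeric matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop(what, " must be symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  if (any(abs(diag(m) - 1) > 1e-8))
    stop(what, " must have all diagonal entries equal to 1", call. = FALSE)
  if (any(m < -1 - 1e-8) || any(m > 1 + 1e-8))
    stop(what, " entries must lie in [-1, 1]", call. = FALSE)
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop(what, " must be positive semi-definite (smallest eigenvalue ",
         format(ev), ")", call. = FALSE)
  invisible(m)
}

#' Build a correlation matrix from a structure expression
#'
#' Expands the short structure expressions used throughout the package
#' wherever a correlation matrix is expected:
#' \describe{
#'   \item{`"ar1(a)"`}{first-order autoregressive, entries `a^|i-j|`,
#'     with `a` in (-1, 1);}
#'   \item{`"toeplitz"`}{linearly declining Toeplitz band, entries
#'     `max(0, 1 - |i-j|/dim)`;}
#'   \item{`"I"`}{the identity (independence).}
#' }
#' The Toeplitz decline rate is this package's convention; pass a numeric
#' matrix instead to use any other band.
#'
#' @param expr structure expression string.
#' @param dim matrix dimension (>= 1).
#' @return a `dim` x `dim` correlation matrix.
#' @examples
#' parseCovStructure("ar1(0.5)", 3)
#' parseCovStructure("I", 4)
#' @export
parseCovStructure <- function(expr, dim) {
  if (!is.character(expr) || length(expr) != 1L)
    stop("structure expression must be a single string", call. = FALSE)
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("dim must be a positive integer",
                                   call. = FALSE)
  e <- trimws(expr)
  idx <- abs(outer(seq_len(dim), seq_len(dim), "-"))
  if (e == "I") {
    m <- diag(dim)
  } else if (e == "toeplitz") {
    m <- matrix(pmax(0, 1 - idx / dim), dim, dim)
  } else if (grepl("^ar1\\(", e)) {
    inner <- sub("^ar1\\((.*)\\)$", "\\1", e)
    if (identical(inner, e))
      stop("malformed structure expression: '", expr,
           "' (expected closing parenthesis)", call. = FALSE)
    a <- suppressWarnings(as.numeric(trimws(inner)))
    if (is.na(a))
      stop("malformed structure expression: '", expr,
           "' (token '", inner, "' is not a number)", call. = FALSE)
    if (a <= -1 || a >= 1)
      stop("ar1 parameter must lie in (-1, 1), got ", a, call. = FALSE)
    m <- a^idx
  } else {
    stop("unknown structure expression: '", expr,
         "' (expected one of \"ar1(a)\", \"toeplitz\", \"I\")",
         call. = FALSE)
  }
  checkCorrelationMatrix(m, paste0("structure '", expr, "'"))
  m
}

#' Build a block-diagonal LD matrix
#'
#' Splits M SNPs into `s` independent LD blocks and fills each block with
#' the structure given by `expr` (see [parseCovStructure()]). When `s` does
#' not divide M, the first `M %% s` blocks receive one extra SNP.
#' Cross-block entries are exactly zero.
#'
#' @param expr structure expression string, or a numeric correlation matrix
#'   used directly (then `s` must be 1).
#' @param M total number of SNPs.
#' @param s number of independent blocks (1 <= s <= M).
#' @return an M x M correlation matrix.
#' @examples
#' buildBlockLD("ar1(0.8)", M = 4, s = 2)
#' @export
buildBlockLD <- function(expr, M, s = 1L) {
  M <- as.integer(M); s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("s must be a positive integer", call. = FALSE)
  if (s > M) stop("number of LD blocks s (", s,
                  ") cannot exceed the number of SNPs M (", M, ")",
                  call. = FALSE)
  if (is.matrix(expr)) {
    if (s != 1L)
      stop("a numeric LD matrix cannot be combined with s > 1", call. = FALSE)
    if (nrow(expr) != M)
      stop("numeric LD matrix must be M x M", call. = FALSE)
    return(checkCorrelationMatrix(expr, "LD matrix"))
  }
  sizes <- rep(M %/% s, s)
  extra <- M %% s
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- matrix(0, M, M)
  at <- 0L
  for (sz in sizes) {
    idx <- at + seq_len(sz)
    out[idx, idx] <- parseCovStructure(expr, sz)
    at <- at + sz
  }
  out
}

## internal: symmetric PSD square root (tolerates zero / near-zero
## eigenvalues where chol() would fail, e.g. h = 0 or singular residual
## covariances)
matSqrt <- function(m) {
  if (length(m) == 1L) return(matrix(sqrt(max(m, 0)), 1L, 1L))
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

isIdentity <- function(m) {
  nrow(m) == ncol(m) && max(abs(m - diag(nrow(m)))) == 0
}
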