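## Plain-text serialization of simulated datasets and the scatter-data
## export backing the summary visualization.

fmtNum <- function(x) formatC(x, digits = 17, format = "g")

writeMatrixTSV <- function(m, path) {
  df <- as.data.frame(apply(as.matrix(m), 2L, fmtNum, simplify = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

readMatrixTSV <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "numeric", check.names = FALSE))
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Serializes an [MRDataset-class] as tab-separated tables: `ivs.tsv` (one
#' row per IV: index, type, outcome estimates/SEs and per-exposure
#' exposure estimates/SEs, standardized and unstandardized), matrix files
#' `ld_matrix.tsv`, `ld_hat_matrix.tsv` and `rho_me.tsv` (outcome-first
#' convention), `theta.tsv`, and `metadata.yaml` holding the engine, seed
#' and the complete generating parameters. Numbers are written with 17
#' significant digits, so [readDataset()] round-trips bit-exactly and
#' re-running the engine from the metadata reproduces the dataset.
#'
#' @param ds an [MRDataset-class] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "MRDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  p <- nExposures(ds)
  tab <- data.frame(iv_index = ds@ivIndex, IVType = ds@ivType,
                    by = fmtNum(ds@by), byse = fmtNum(ds@byse),
                    by_unstd = fmtNum(ds@byUnstd),
                    byse_unstd = fmtNum(ds@byseUnstd),
                    check.names = FALSE)
  for (k in seq_len(p)) {
    tab[[paste0("bx", k)]] <- fmtNum(ds@bx[, k])
    tab[[paste0("bxse", k)]] <- fmtNum(ds@bxse[, k])
    tab[[paste0("bx", k, "_unstd")]] <- fmtNum(ds@bxUnstd[, k])
    tab[[paste0("bxse", k, "_unstd")]] <- fmtNum(ds@bxseUnstd[, k])
  }
  files <- file.path(dir, c("ivs.tsv", "ld_matrix.tsv", "ld_hat_matrix.tsv",
                            "rho_me.tsv", "theta.tsv", "metadata.yaml"))
  utils::write.table(tab, files[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeMatrixTSV(ds@ldMatrix, files[2L])
  writeMatrixTSV(ds@ldHatMatrix, files[3L])
  writeMatrixTSV(ds@rhoME, files[4L])
  writeLines(c("theta", fmtNum(ds@theta)), files[5L])
  meta <- list(
    package = "MRsim",
    version = as.character(utils::packageVersion("MRsim")),
    engine = ds@meta$engine, seed = ds@meta$seed,
    n_iv = nIV(ds), mean_f = as.numeric(ds@meta$meanF),
    written = format(Sys.time(), tz = "UTC"),
    params = if (is.null(ds@params)) NULL else paramsAsList(ds@params))
  yaml::write_yaml(meta, files[6L])
  invisible(files)
}

#' Read a dataset written by [writeDataset()]
#'
#' Reconstructs the per-IV tables, LD matrices, error-correlation matrix
#' and causal effects bit-exactly. The full-truth and parameter slots are
#' restored from the metadata when present (`truth` itself is not
#' serialized; regenerate from the metadata parameters to recover it).
#'
#' @param dir directory produced by [writeDataset()].
#' @return an [MRDataset-class] object.
#' @export
readDataset <- function(dir) {
  f <- function(x) file.path(dir, x)
  tab <- utils::read.table(f("ivs.tsv"), sep = "\t", header = TRUE,
                           check.names = FALSE)
  meta <- yaml::read_yaml(f("metadata.yaml"))
  p <- sum(grepl("^bx[0-9]+$", names(tab)))
  num <- function(col) as.numeric(tab[[col]])
  grab <- function(stub) {
    matrix(unlist(lapply(seq_len(p), function(k)
      num(paste0(stub[1L], k, stub[2L])))), ncol = p)
  }
  theta <- as.numeric(readLines(f("theta.tsv"))[-1L])
  params <- if (!is.null(meta$params)) paramsFromList(meta$params) else NULL
  new("MRDataset",
      ivIndex = as.integer(tab$iv_index),
      bx = grab(c("bx", "")), bxse = grab(c("bxse", "")),
      by = num("by"), byse = num("byse"),
      bxUnstd = grab(c("bx", "_unstd")), bxseUnstd = grab(c("bxse", "_unstd")),
      byUnstd = num("by_unstd"), byseUnstd = num("byse_unstd"),
      ivType = as.character(tab$IVType), theta = theta,
      rhoME = unname(readMatrixTSV(f("rho_me.tsv"))),
      ldMatrix = unname(readMatrixTSV(f("ld_matrix.tsv"))),
      ldHatMatrix = unname(readMatrixTSV(f("ld_hat_matrix.tsv"))),
      truth = NULL, params = params,
      meta = list(engine = meta$engine, seed = meta$seed,
                  nref = if (is.null(params)) NA else params@nref,
                  meanF = as.numeric(meta$mean_f)))
}

#' Export scatter data for the standard summary plot
#'
#' Long-format table of estimated SNP-exposure (x) against SNP-outcome (y)
#' associations, one facet per exposure, each row labelled with the IV
#' type. With more than one exposure an additional `linear_predictor`
#' facet plots the multivariable linear predictor `bx %*% thetaHat`
#' (thetaHat the IVW estimate) against `by`; for valid instruments these
#' points lie near the unit-slope line through the origin.
#'
#' @param ds an [MRDataset-class] object.
#' @return data.frame with columns `facet`, `x`, `y`, `ivType`.
#' @export
exportScatterData <- function(ds) {
  stopifnot(is(ds, "MRDataset"))
  p <- nExposures(ds)
  out <- do.call(rbind, lapply(seq_len(p), function(k) {
    data.frame(facet = paste0("exposure_", k), x = ds@bx[, k], y = ds@by,
               ivType = ds@ivType, stringsAsFactors = FALSE)
  }))
  if (p > 1L) {
    est <- ivwEstimate(ds)
    lp <- as.numeric(ds@bx %*% est$thetaHat)
    out <- rbind(out, data.frame(facet = "linear_predictor", x = lp,
                                 y = ds@by, ivType = ds@ivType,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Plot simulated MR data
#'
#' Thin cosmetic layer over [exportScatterData()]: scatterplots of
#' SNP-exposure against SNP-outcome association estimates, colored by IV
#' type. Requires ggplot2.
#'
#' @param ds an [MRDataset-class] object.
#' @return a ggplot object.
#' @export
plotSimData <- function(ds) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSimData() needs the ggplot2 package; ",
         "use exportScatterData() for the underlying table", call. = FALSE)
  d <- exportScatterData(ds)
  x <- y <- ivType <- NULL  # quiet R CMD check; columns of d
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y, color = ivType)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~facet, scales = "free_x") +
    ggplot2::labs(x = "SNP-exposure association",
                  y = "SNP-outcome association", color = "IV type") +
    ggplot2::theme_minimal()
}
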