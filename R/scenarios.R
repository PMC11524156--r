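## Packaged default simulation scenarios: five pleiotropy/instrument
## regimes crossed with sample size, overlap, SNP count and exposure count.

scenarioKinds <- c("chp", "uhp", "uhp_chp", "weak_ivs", "uhp_chp_weak_ivs")

#' List the default scenario names
#'
#' The default grid crosses five regimes — CHP only, UHP only, UHP + CHP,
#' weak IVs, and UHP + CHP + weak IVs — with GWAS sample size (30K or
#' 100K), exposure/outcome sample overlap (0% or 100%), number of causal
#' SNPs (100 or 500) and number of exposures (1 or 3): 80 named bundles.
#'
#' @return character vector of scenario names accepted by
#'   [defaultSetup()].
#' @examples
#' head(listScenarios())
#' length(listScenarios())  # 80
#' @export
listScenarios <- function() {
  g <- expand.grid(p = c(1L, 3L), M = c(100L, 500L), ov = c(0L, 100L),
                   n = c("30k", "100k"), kind = scenarioKinds,
                   stringsAsFactors = FALSE)
  sprintf("%s_n%s_overlap%d_m%d_p%d", g$kind, g$n, g$ov, g$M, g$p)
}

#' Build a packaged default parameter bundle
#'
#' Resolves a scenario name from [listScenarios()] to a fully validated
#' [SummaryParams-class] bundle. Shared defaults: heritability 0.3 per
#' exposure, causal effects 0.2 (p = 1) or (0.2, 0.1, -0.1) (p = 3),
#' phenotypic correlations 0.3, no LD (`R = "I"`), exact reference-panel
#' LD. Pleiotropy regimes set 30% of SNPs to the named type (20% each when
#' combined) with variance fraction 0.3 and `zetaC = -0.5`; winner's-curse
#' regimes select at `tau = 5e-8`; weak-IV regimes calibrate to mean F 10.
#'
#' @param name a scenario name.
#' @param seed RNG seed stored in the bundle (default 1).
#' @return a [SummaryParams-class] object.
#' @examples
#' defaultSetup("uhp_n100k_overlap0_m500_p3")
#' @export
defaultSetup <- function(name, seed = 1L) {
  all <- listScenarios()
  if (!is.character(name) || length(name) != 1L || !(name %in% all))
    stop("unknown scenario '", name, "'; available scenarios:\n  ",
         paste(sort(all), collapse = "\n  "), call. = FALSE)
  m <- regmatches(name, regexec(
    "^(.*)_n(30k|100k)_overlap(0|100)_m(100|500)_p(1|3)$", name))[[1L]]
  kind <- m[2L]
  n <- if (m[3L] == "30k") 3e4 else 1e5
  ov <- as.numeric(m[4L]) / 100
  M <- as.integer(m[5L])
  p <- as.integer(m[6L])

  weak <- grepl("weak_ivs", kind)
  hasU <- grepl("uhp", kind)
  hasC <- grepl("chp$", kind) || grepl("_chp_|^chp", kind)
  frac <- if (hasU && hasC) 0.2 else 0.3
  mU <- if (hasU) as.integer(round(frac * M)) else 0L
  mC <- if (hasC) as.integer(round(frac * M)) else 0L

  summaryParams(
    theta = if (p == 1L) 0.2 else c(0.2, 0.1, -0.1),
    M = M, p = p, nx = n, nY = n, kxY = ov,
    Kxx = matrix(pmax(ov, diag(p)), p, p), RxY = 0.3, h = 0.3,
    mU = mU, mC = mC,
    rhoU = if (hasU) 0.3 else 0, rhoC = if (hasC) 0.3 else 0,
    zetaC = -0.5, kappa2 = 1,
    simType = if (weak) "weak_ivs" else "winners_curse",
    stdType = "z",
    tau = if (weak) 1 else 5e-8, Ftarget = 10,
    R = "I", s = 1L, nref = Inf, seed = seed)
}
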