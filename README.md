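# MRsim

MRsim generates GWAS summary statistics for benchmarking Mendelian
randomization (MR) estimators. MR infers the causal effect θ of exposures
*x* on an outcome *Y* from per-SNP association estimates and standard
errors; whether an MR method works in practice depends on how it copes
with horizontal pleiotropy, overlapping GWAS samples, weak instruments,
winner's-curse selection, and linkage disequilibrium (LD) estimated from
finite reference panels. MRsim synthesizes complete MR datasets with
controlled amounts of each of these, in both the univariable and
multivariable settings, so competing estimators can be compared under
identical, reproducible conditions.

## Model

Data are generated from a structural model with a confounder *U*:

    U = g'γ_C + ε_U
    x = B'g + π_x U + ε_x
    Y = x'θ + π_Y U + g'γ_U + ε_Y   =   α'g + ε̄_Y,

with standardized genotypes *g*, true SNP–exposure effects **B**
(heritability h per exposure), uncorrelated pleiotropy γ_U (direct
SNP→outcome paths), correlated pleiotropy γ_C (paths through *U*), and
the exact identity α = Bθ + γ_U + γ_C. Two engines produce summary data:

* `generateSummary()` draws standardized estimates directly from their
  sampling distributions, including the estimation-error covariance
  Ω_ij = k_ij·min(n_i,n_j)·ρ_ij/(n_i·n_j) implied by sample overlap,
  χ²-distributed squared standard errors, and Wishart reference-panel LD
  noise — sub-second even at thousands of SNPs.
* `generateIndividual()` simulates genotypes and phenotypes from the model
  above and runs per-SNP OLS GWAS on (possibly overlapping) samples.

Both support winner's-curse IV selection (p-value threshold τ with greedy
LD pruning at r² ≤ κ²) or weak-instrument sets calibrated to a target
mean F-statistic, and return an `MRDataset` with standardized and
unstandardized `bx/bxse/by/byse`, IV-type labels, true and estimated LD
matrices, the true θ, and the error-correlation matrix `RhoME`
(outcome-first convention). See the methods vignette
(`vignettes/mr-simulation-methods.Rmd`) for the full model and every
numerical convention.

## Worked example

```r
library(MRsim)
sp <- summaryParams(theta = c(0.2, 0.1, -0.1), M = 200, p = 3,
                    nx = 1e5, nY = 1e5, h = 0.3,
                    mU = 30, rhoU = 0.3,      # 30 UHP SNPs, variance fraction 0.3
                    kxY = 1, RxY = 0.3,       # complete overlap, phenotypic corr 0.3
                    seed = 42)
ds <- generateSummary(sp)
ds
#> MRDataset (summary engine): 200 IVs, 3 exposures
#>   IV types:  valid=170, UHP=30, CHP=0
#>   theta:     0.2, 0.1, -0.1
#>   mean F:    132.9, 171.9, 155.9
#>   LD:        nref = Inf (exact)
ivwEstimate(ds, subset = which(ivType(ds) == "valid"))$thetaHat
#> [1]  0.20790  0.09802 -0.09441
rhoME(ds)[1, ]
#> [1] 1.0 0.3 0.3 0.3
```

The valid-instrument IVW estimate recovers the generating effects
(0.2, 0.1, −0.1) within sampling error; `rhoME` reports the
estimation-error correlation (here 0.3 for each exposure against the
outcome: complete overlap × phenotypic correlation 0.3) that
overlap-aware MR methods consume. `table(ivType(ds))` gives the labels an
evaluation needs to score pleiotropy-robust estimators.

Eighty packaged parameter bundles cover common regimes:

```r
listScenarios()                      # 5 regimes x {30K,100K} x overlap x M x p
ds <- generateSummary(defaultSetup("uhp_chp_n30k_overlap100_m100_p1"))
writeDataset(ds, "out/")             # TSV tables + metadata.yaml (round-trips)
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/mrsim` (`simulate`, `scenarios`, `plotdata` subcommands).

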