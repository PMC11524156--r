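---
title: "Simulating GWAS summary statistics for Mendelian randomization: models and methods"
author: "MRsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GWAS summary statistics for MR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MRsim)
```

# The problem MRsim addresses

Mendelian randomization (MR) estimates the causal effect $\theta$ of one or
more exposures $x$ on an outcome $Y$ using genetic variants as instruments.
In practice MR runs on GWAS summary statistics: per-SNP association
estimates $\hat\beta_{jk}$ (SNP $j$, exposure $k$) and $\hat\alpha_j$
(SNP–outcome) with standard errors. New MR estimators are validated by
simulation, and the phenomena that break MR in practice — horizontal
pleiotropy, overlapping GWAS samples, weak instruments, winner's curse,
linkage disequilibrium (LD) and its imprecise reference-panel estimation —
must be generated faithfully for those validations to mean anything.
MRsim is a simulation engine for exactly that: it synthesizes complete MR
summary datasets under controlled amounts of each phenomenon, in both the
univariable and multivariable settings. It consumes no biological data;
SNPs are abstract indices $1..M$.

# Structural model

Both engines are grounded in one data-generating DAG with a scalar
confounder $U$:

$$U = g^\top\gamma_C + \epsilon_U,\qquad
  x = B^\top g + \pi_x U + \epsilon_x,\qquad
  Y = x^\top\theta + \pi_Y U + g^\top\gamma_U + \epsilon_Y,$$

where $g$ are standardized genotypes, $B$ ($M \times p$) are true
SNP–exposure effects, $\gamma_U$ are *uncorrelated* horizontal pleiotropy
(UHP) effects (direct SNP-to-outcome paths), and $\gamma_C$ are
*correlated* horizontal pleiotropy (CHP) effects acting through the
confounder. All phenotypes have mean 0 and variance 1. The reduced form
is $Y = \alpha^\top g + \bar\epsilon_Y$ with
$\alpha = B\theta + \gamma_U + \gamma_C$ (the identity holds exactly in
every dataset the package produces, so "valid" SNPs satisfy
$\alpha_j = \beta_j^\top\theta$). UHP, CHP and valid SNPs occupy mutually
exclusive index blocks ($1..m_U$, $m_U+1..m_U+m_C$, rest), fixed before
instrument selection so labels survive subsetting.

# The two engines

## Summary-statistic engine (`generateSummary()`)

Draws estimates directly from their sampling distributions:

1. **Error covariance.** For studies $i,j$ with sample sizes $n_i,n_j$,
   overlap proportion $k_{ij}$ and phenotypic correlation $\rho_{ij}$, the
   per-SNP estimation errors on the standardized scale have covariance
   $\Omega_{ij} = n_{ij}\rho_{ij}/(n_i n_j)$ with shared count
   $n_{ij} = k_{ij}\min(n_i,n_j)$, and variance $1/n_i$. This is the
   standard overlapping-samples result for standardized per-SNP OLS
   estimates; the test suite verifies it against an independent
   Monte-Carlo oracle that actually runs OLS on partially shared samples.
   The shared-count convention $k\cdot\min(n_i,n_j)$ guarantees the
   implied overlap never exceeds the smaller study. The correlation form
   `RhoME` (outcome in the first row/column throughout) is reported for
   downstream estimators that model error correlation.
2. **True effects.** $\mathrm{vec}(B) \sim N(0, M^{-1}\Sigma_{\beta\beta}
   \otimes R)$, with $\Sigma_{\beta\beta} = D R_{\beta\beta} D$,
   $D = \mathrm{diag}(\sqrt{h_1},\dots,\sqrt{h_p})$, so column $k$
   explains heritability $h_k$ in expectation and rows carry the LD
   structure $R$. When $R = I$ the draw reduces to independent rows (same
   distribution, cheaper).
3. **Pleiotropy.** UHP effects are $N(0, M^{-1}\rho_U\,
   \theta^\top\Sigma_{\beta\beta}\theta)$ on their support: $\rho_U$ is
   the variance of the UHP effects relative to the mediated effects
   $B\theta$. CHP adds, on its own support, the same-style noise with
   fraction $\rho_C$ *plus* the shift $(B\theta)_j(-1+\zeta_C)$, which
   makes $\mathrm{cor}(B\theta, \gamma_C)$ negative by default
   ($\zeta_C = -0.5$). $\zeta_C \in (-1, 1]$; $\zeta_C = 1$ cancels the
   shift (pure random CHP). The shift is applied only on the CHP support
   (masking after addition), so valid SNPs keep the exact identity above.
4. **Noise.** Estimation errors are i.i.d. rows
   $N(0, \Omega)$ added to $(\alpha, B)$; squared standard errors are
   drawn as $\chi^2_{n-1}/(n(n-1))$ so that $E[\widehat{SE}^2] = 1/n$,
   the only scaling consistent with variance-1 phenotypes and genotypes.
5. **Selection, standardization, LD estimation** — shared with the other
   engine, below.

## Individual-level engine (`generateIndividual()`)

Simulates the DAG literally. Genotypes are marginally
$\mathrm{Binomial}(2, \mathrm{maf})$ (default maf 0.3) and standardized
empirically; under LD the two allele draws come from a latent Gaussian
copula thresholded at the maf quantile. Thresholding attenuates the
latent correlation — the package uses $R$ itself as the latent
correlation and *measures* the attenuation in its test suite (via a
quadrature oracle for the thresholded-pair correlation) rather than
inverting it; with the default maf the realized LD is a few percent below
the nominal $R$.

Uniform$(-1,1)$ pleiotropy effects are rescaled against the realized
genotype covariance so the CHP SNPs explain exactly
$\sigma^2_{\gamma_C}$ of $\mathrm{Var}(U)$ and the UHP SNPs exactly
$\sigma^2_{\gamma_U}$ of $\mathrm{Var}(Y)$. Exposure effects are a matrix
normal draw whose columns are then rescaled so
$\mathrm{diag}(B^\top B)_k = h_k$ *exactly* (machine precision).

**Solving the path coefficients.** The user specifies
$\mathrm{Cov}(x\,|\,U)$, the per-exposure conditional outcome variances
$\mathrm{Var}(Y\,|\,U, x_k)$, and the signs of $\theta$. Moment matching
then fixes everything:

* $\mathrm{Cov}(x_k, U) = \sqrt{1 - \mathrm{Cov}(x|U)_{kk}}$ (nonnegative
  root), giving $\pi_{x,k}$ in closed form and the exposure residual
  covariance by subtraction; a negative residual variance anywhere raises
  an error naming the exposure.
* $|\theta_k|$ and $\pi_Y$ are solved numerically from the $p$ equations
  $\mathrm{Var}(Y|U,x_k) = t_k$ (exact Gaussian conditioning on the
  model-implied joint covariance, with the outcome residual variance
  substituted as the unit-variance slack). These equations identify
  $\theta$ but leave a one-dimensional trade-off between $\pi_Y$ and the
  outcome residual — with unconfounded exposures the split is not even
  observable. The package resolves it by anchoring: $\pi_Y$ starts at
  $-1$ scaled back by the exposures' average confounded share,
  $-\sqrt{\mathrm{mean}_k(1 - \mathrm{Cov}(x|U)_{kk})}$, and the solution
  on the target manifold closest to that anchor is taken (quadratic
  penalty with weight $10^{-6}$; targets are still matched to
  $\le 10^{-8}$, else an infeasibility error). The anchor vanishes when
  the exposures are unconfounded, so the no-effect limit collapses to
  pure noise.
* `Rxx`, if supplied, is only checked for consistency with the
  correlations implied by $\mathrm{Cov}(x|U)$ (warning above a 0.02
  deviation); it is not a second constraint, since the two jointly
  overdetermine the same covariance.

GWAS is per-SNP simple OLS with intercept and the $n-2$ standard-error
denominator. The exposure and outcome samples share
$\mathrm{round}(p_{01}\min(n_0,n_1))$ individuals — deterministically the
first indices of each set, so randomness lives in the draws, not the
bookkeeping. All exposure GWAS share one sample; arbitrary
exposure-by-exposure overlap patterns are the summary engine's job. The
reported `RhoME` is computed analytically from
$(p_{01}, n_0, n_1)$ and the model-implied phenotypic correlations, since
its role downstream is an input to MR methods, not an estimate.

## Instrument selection, standardization, LD estimation (shared)

`simType` toggles two mutually exclusive selection paths:

* **`winners_curse`** — a SNP is a candidate iff its minimum Wald p-value
  across exposures is below $\tau$ (the union of exposure-specific
  instrument sets, the multivariable convention); candidates are greedily
  LD-pruned at $r^2 \le \kappa^2$, most significant first, ties to the
  lower index (standard clumping priority). Selecting on the same
  estimates that are reported is precisely what creates winner's-curse
  bias, and a directional test verifies the selected $|\hat\beta_x|$
  exceed the selected true $|\beta_x|$ on average.
* **`weak_ivs`** — after LD pruning, the set is calibrated to a target
  mean F-statistic by repeatedly excluding the SNP with the largest
  per-SNP F (averaged across exposures) while the mean exceeds the
  target, stopping at the step whose achieved mean F is closest to the
  target. Since the largest value is removed each time, the mean-F
  trajectory is strictly decreasing; if the initial mean F is already at
  or below the target the full set is returned with a warning. The
  F-statistic is the marginal mean squared z per exposure (not a
  conditional, Sanderson–Windmeijer-style F, which is out of scope).

Standardization is `"z"` ($b = z/\sqrt{n}$, $se = 1/\sqrt{n}$; z-scores
and F-statistics are preserved exactly) or `"none"`; both the
standardized and unstandardized blocks are always returned. Finally the
true LD of the selected set is degraded to a reference-panel estimate by
a $\mathrm{Wishart}(n_{ref}, R_S)$ draw standardized back to a
correlation matrix (the Wishart scale convention cancels in the
standardization); $n_{ref} = \infty$ returns $R_S$ unchanged, bit-exact.

# Parameters that matter, with defaults

| Parameter | Meaning | Default |
|---|---|---|
| `h` | SNP heritability per exposure (unit-variance scale) | 0.3 |
| `theta` | causal effect(s) | required |
| `mU`, `mC`, `rhoU`, `rhoC` | pleiotropy SNP counts / variance fractions | 0 |
| `zetaC` | CHP sign-correlation control in $(-1,1]$ | $-0.5$ |
| `kxY`, `Kxx` | overlap proportions (outcome/exposure pairs) | 0 / $I$ |
| `RxY` | phenotypic correlations, outcome first | 0.3 off-diagonal |
| `tau`, `kappa2` | p-value and $r^2$ selection thresholds | 1, 1 (no selection) |
| `Ftarget` | target mean F for `weak_ivs` | 10 |
| `R`, `s` | LD structure and number of independent blocks | `"I"`, 1 |
| `nref` | LD reference-panel size | `Inf` (exact LD) |
| `maf` | allele frequency, individual engine | 0.3 |

Covariance structures can be written as `"ar1(a)"` (entries $a^{|i-j|}$),
`"toeplitz"`, or `"I"` anywhere a correlation matrix is expected. No
decay rate is canonical for a Toeplitz band, so the package uses the
linear decline $\max(0, 1 - |i-j|/\mathrm{dim})$; pass a numeric matrix
for any other band. When $s$ LD blocks do not divide $M$, the first
$M \bmod s$ blocks take one extra SNP.

The packaged scenario grid (`listScenarios()`, 80 bundles) crosses five
regimes (CHP, UHP, UHP+CHP, weak IVs, UHP+CHP+weak IVs) with sample size
(30K/100K — read as thousands; a GWAS of 30 people is not meaningful),
overlap (0/100%), SNP count (100/500) and exposure count (1/3). Values
the regime names do not pin down were chosen once as field-typical:
heritability 0.3, causal effects 0.2 (univariable) or $(0.2, 0.1, -0.1)$,
pleiotropy on 30% of SNPs (20% each when combined) at variance fraction
0.3, phenotypic correlations 0.3, $\tau = 5\times 10^{-8}$ (genome-wide
significance) for winner's-curse regimes, mean-F target 10 for weak-IV
regimes.

# Reproducibility and numerical choices

Every engine run is a pure function of (parameters, seed): each draw type
(exposure effects, UHP, CHP, estimation errors, per-study standard
errors, genotypes, phenotypes, Wishart LD) runs in its own named RNG
substream derived from the master seed, so draws are bit-reproducible and
mutually stream-independent. Degenerate inputs are handled explicitly:
zero heritability gives zero effect columns; positive-semidefinite (not
strictly definite) covariances go through a symmetric eigenvalue square
root rather than a Cholesky; an empty instrument set after selection
raises a structured error advising threshold relaxation rather than an
empty dataset; a finite $n_{ref}$ not exceeding $|S|$ is rejected (the
Wishart draw would be singular).

# Worked example

```{r example}
sp <- summaryParams(theta = c(0.2, 0.1, -0.1), M = 200, p = 3,
                    nx = 1e5, nY = 1e5, h = 0.3,
                    mU = 30, rhoU = 0.3, kxY = 1, RxY = 0.3, seed = 42)
ds <- generateSummary(sp)
ds
ivwEstimate(ds, subset = which(ivType(ds) == "valid"))$thetaHat
rhoME(ds)[1, ]
```

The IVW estimate on the valid instruments recovers `theta` within
sampling error, while the full-set estimate is biased by the UHP SNPs —
which is exactly the contrast MR-method benchmarks need.

# What the generator emulates — and what it does not

The synthetic data reproduce the features that drive MR estimator
behavior: correlated estimation errors from sample overlap, the mediated
versus pleiotropic decomposition of SNP–outcome effects, LD-induced
correlation of effects and estimates, reference-panel LD noise,
selection-induced winner's curse, and weak-instrument regimes. They do
not emulate: allele-frequency-dependent standard-error heterogeneity
(all SNPs share the $1/n$ scale of standardized genotypes), genome-wide
null SNPs with exactly zero effects (estimators needing a null background
must source it elsewhere), case-control outcomes (all traits are
continuous), genomic coordinates (no distance-based clumping), or
population structure. Passing tests therefore demonstrate correctness of
the stated sampling models, not realism of any particular GWAS.

Known limitations: the copula LD for genotypes is attenuated relative to
the nominal $R$ (measured, not corrected); the individual engine's
confounder-to-outcome path is identified only up to the documented
anchor; conditional F-statistics and Steiger filtering are out of scope.

# Problem sizes used in the test suite

The automated checks run at deliberately moderated sizes chosen to make
Monte-Carlo tolerances meaningful: up to $M = 10^4$ SNPs for moment
checks, $n = 2\times 10^5$ individuals for the unit-variance contract,
200–500 replicates for coverage/type-I calibration, and 1000 randomized
instances for the LD-pruning invariant. These sizes are the package's own
trade-off between statistical resolution and turnaround.
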