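Package: MRsim
Title: Simulation Engine for Univariable and Multivariable Mendelian
    Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates genome-wide association study (GWAS) summary
    statistics for benchmarking Mendelian randomization (MR) estimators.
    Two engines are provided: a fast engine that draws standardized
    per-SNP association estimates directly from their sampling
    distributions, and an individual-level engine that simulates
    genotypes, a confounder, exposures and an outcome from a structural
    equation model and then performs per-SNP ordinary least squares GWAS.
    Both engines support uncorrelated and correlated horizontal
    pleiotropy, arbitrary exposure/outcome sample overlap with the implied
    estimation-error covariance, linkage disequilibrium among instruments
    with Wishart reference-panel estimation noise, winner's-curse
    instrument selection at a p-value threshold, and weak-instrument sets
    calibrated to a target mean F-statistic, in both the single-exposure
    and multiple-exposure settings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'covstruct.R'
    'params.R'
    'noise.R'
    'summary_engine.R'
    'individual_engine.R'
    'selection.R'
    'io.R'
    'scenarios.R'
    'ivw.R'
    'MRsim-package.R'
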