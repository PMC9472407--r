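Package: prsport
Title: Polygenic Risk Score Portability Analysis Across Populations
Version: 0.1.0
Authors@R: person("MADCaP", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: Tools to study how well polygenic risk scores (PRS) transfer
    between continental populations, motivated by prostate cancer
    case/control studies. Implements proxy-based score resolution with
    r-squared-adjusted weights, per-site mean imputation of missing doses,
    PRS computation and standardization, a joint site-frequency-spectrum
    ("bow-tie") binomial informativeness test, EHH/iHS selection-signature
    statistics with Kolmogorov-Smirnov uniformity testing of percentiles,
    genotype PCA, classical MDS, sample QC, and ROC-AUC evaluation with
    DeLong variances, covariate-adjusted odds ratios and aggressiveness
    classifiers. A synthetic-data module generates two-population
    case/control cohorts under a Balding-Nichols drift plus
    liability-threshold disease model so the full pipeline is testable
    without restricted genotype data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
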