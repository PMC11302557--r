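Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization with
    GWAS summary statistics: instrument selection (significance, minor
    allele frequency, LD clumping, F-statistic screens), exposure/outcome
    allele harmonization with palindromic-SNP exclusion, five causal-effect
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode), pleiotropy and heterogeneity diagnostics
    (Cochran's Q, Egger intercept test, MR-PRESSO with iterative outlier
    removal, leave-one-out), and per-rank Bonferroni reporting. A synthetic
    summary-statistic generator with known ground truth makes every stage
    testable without external GWAS downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'harmonize.R'
    'estimators.R'
    'summary-io.R'
    'instruments.R'
    'mrpipe-package.R'
    'sensitivity.R'
    'pipeline.R'
    'synthetic-gwas.R'
    'utils.R'
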