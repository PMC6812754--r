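Package: sexmr
Title: Sex-Stratified Mendelian Randomization with Genetic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sex-stratified Mendelian randomization of continuous
    exposures on disease outcomes using genetic risk score instruments.
    Implements instrument construction from per-variant summary statistics
    (quality control, window and linkage-disequilibrium pruning, allele
    orientation, sex-specific weighting), phenotype preparation (blood-pressure
    medication correction, rank inverse-normal transformation of covariate
    residuals, smoking-status derivation), regression-based association
    screening with Bonferroni test families, individual-level Wald-ratio
    estimation with delta-method standard errors, two-sample summary-data
    estimators (inverse-variance weighted, MR-Egger, weighted median), and
    Cochran's Q tests of male-female heterogeneity. A synthetic-cohort
    generator with known sex-specific causal structure supports end-to-end
    validation without access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), yaml, jsonlite, vcfR
Config/testthat/edition: 3
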