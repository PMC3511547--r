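Package: imputeval
Title: Evaluation of Genotype Imputation Accuracy and Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Framework for assessing genotype imputation performance in
    admixed study populations. Provides chance-corrected accuracy statistics
    for masked-SNP experiments (concordance and the kappa-style imputation
    quality score), the dosage variance-ratio estimate of imputation quality
    (r2hat) with minor-allele-frequency-stratified summaries, standard
    pre-imputation quality control (Hardy-Weinberg exact test, call-rate and
    frequency filters, duplicate and relatedness pruning with the
    stratification-robust kinship estimator, ancestry-proportion filtering),
    reference-panel composition with filtering of SNPs monomorphic in a
    subpanel, and a synthetic-data module (Balding-Nichols population
    divergence, two-way admixture, and a parameterized imputation channel)
    that emulates the structure of an admixed genome-wide study so the whole
    pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
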