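Package: ithbench
Title: Reliability and Prognostic Value of Intra-Tumor Heterogeneity Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how reliably intra-tumor heterogeneity (ITH) can be
    estimated from single-sample whole-exome sequencing and whether it carries
    prognostic value. Provides a synthetic tumor-cohort generator with known clone
    structure (cellular prevalences, purity- and copy-number-dependent variant
    allele fractions with binomial read sampling, nested protected/public mutation
    views, censored survival), somatic SNV filtering rules, per-sample ITH feature
    summaries including the MATH score, reconstruction-agreement metrics between
    subclonal reconstructions (clone-number adequacy, weighted Wasserstein distance
    on cancer-cell-fraction distributions, rescaled co-clustering agreement from
    Pearson, Matthews and V-measure coefficients), and a ranking support vector
    machine for censored survival with concordance-index evaluation, Noether
    testing, Fisher aggregation across cross-validation folds and
    Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
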