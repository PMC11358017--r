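Package: resistrank
Title: Rank-Product Meta-Analysis of Immunotherapy-Resistance Genes and
    Calcium Dose-Response Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-cohort rank-product meta-analysis for identifying genes
    consistently up-regulated in tumors that fail to respond to immune
    checkpoint blockade. Provides per-cohort differential expression with
    empirical-Bayes moderated t-statistics, fold-change ranking, the
    rank-product statistic with exact (enumeration), gamma-approximate and
    permutation p-values, Benjamini-Hochberg adjustment, one-sided Fisher
    combination across studies, and a metabolic gene-set filter. Also
    includes downstream immune-context statistics (signature-based cohort
    stratification, per-cell-type cross-dataset correlations, dot-plot
    summaries), Hill-equation EC50 fitting for Fura-2 calcium
    concentration-response data, and a synthetic-data generator that
    emulates multi-cohort responder/non-responder inputs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
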