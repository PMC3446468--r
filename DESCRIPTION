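Package: snpclines
Title: Stratified Case-Control Association and Risk-Allele Clines Along
    Population Axes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether the effect sizes of disease risk
    alleles differ between geographic subgroups of a multi-centre
    case-control study. Implements ancestry-informative-marker quality
    control and a North/South population-axis score, per-collection
    stratified Mantel-Haenszel and DerSimonian-Laird meta-analysis with
    Cochran Q / I-squared heterogeneity, an effect-size-bias battery
    (exact binomial direction test, geometric-mean odds-ratio comparison,
    risk-allele sums, genetic risk scores, weighted correlations against
    the population axis), allele-frequency cline regression, and a seeded
    generator of synthetic multi-collection case-control cohorts with
    frequency clines and subgroup-specific odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, yaml, vcfR, rlang
Suggests: testthat (>= 3.0.0), metafor, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
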