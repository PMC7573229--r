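Package: ktscreen
Title: Low-Potassium Tolerance Screening and Multi-Omics Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Comprehensive evaluation of low-potassium (low-K) tolerance in
    crop germplasm panels and downstream multi-omics response screens. Builds
    low-K tolerance coefficients from replicated trait panels, derives
    principal-component comprehensive indices, fuzzy membership values,
    contribution-rate weights and per-genotype D values, classifies genotypes
    by hierarchical clustering, and selects extreme genotypes by percentile
    rank. Companion stages compute ionome percent-change responses and
    K-utilization-efficiency indices, fit OPLS-DA models with VIP scoring for
    differential-metabolite screening, and apply threshold-based differential
    gene set algebra across contrasting genotypes. A synthetic-data module
    generates trait panels, ionome tables, metabolite matrices and per-gene
    differential tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
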