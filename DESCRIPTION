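Package: raretrio
Title: Integrated Rare-Variant Gene Discovery in Family-Based Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for two-stage gene discovery from rare coding
    variants in family-based cohorts of a common, strongly selected-against
    disorder such as autism. Combines de novo mutation enrichment under
    gene-level mutation-rate models (severity-weighted simulation tests and
    gene-set permutation), transmission disequilibrium tests for ultra-rare
    inherited loss-of-function alleles, pedigree-aware case-control burden
    tests built from pseudocases and pseudocontrols with fractional sample
    sizes, Fisher meta-analysis, mutation-selection-balance estimators of
    selection and effect size, and analytic power and sample-size calculations
    based on the noncentral chi-square distribution. A synthetic cohort
    generator with known per-gene truth (mutation rate, selection coefficient,
    relative risk) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
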