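Package: pleiomr
Title: Sex-Stratified Cross-Trait Pleiotropy, Colocalization and Mendelian
    Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and dissecting shared genetic architecture
    between a primary disease trait and secondary (for example sex-hormone
    related) traits from GWAS summary statistics. Implements conditional
    quantile-quantile fold-enrichment curves, conditional and conjunctional
    false discovery rates (condFDR/conjFDR) for pleiotropic variant discovery,
    LD clumping with tiered prioritization of sex-biased loci (sex
    heterogeneity Z tests and fold-difference rules), Bayesian colocalization
    under the single-causal-variant approximate Bayes factor model for
    cross-trait and xQTL analyses, promoter position-weight-matrix scanning
    with allele-level motif disruption and motif-set enrichment, and a full
    two-sample Mendelian randomization suite (IVW random effects, MR-Egger,
    weighted median and mode, Cochran Q, leave-one-out, a PRESSO-style global
    pleiotropy test, sample-overlap SE adjustment, multivariable MR). A seeded
    synthetic-data generator produces LD-blocked summary statistics, QTL
    regions, and promoter sequences with planted structure for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
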