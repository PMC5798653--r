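Package: mrivw
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with published
    genome-wide association summary statistics. Reads exposure and outcome
    association tables in configurable column dialects, harmonizes effect
    alleles across sources (strand complements, allele swaps, palindromic
    variants) and orients effects to exposure-raising alleles, computes
    per-variant Wald ratio estimates with delta-method standard errors,
    and pools them by fixed-effects inverse-variance weighting with
    Cochran Q and I-squared heterogeneity diagnostics. Includes
    instrument-subset and molar-ratio sensitivity analyses, power
    calculations for binary-outcome Mendelian randomization designs, and
    a generator of paired synthetic summary statistics with known causal
    effects and pleiotropic outliers for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, metafor, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
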