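Package: snprisk
Title: Liability-Scale Variance Explained and Attributable Risk for
    Disease Susceptibility Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how much disease risk is explained by known common
    susceptibility variants in ascertained case-control studies.
    Implements observed-scale R2 from regression of case status on
    risk-allele dosage and its transformation to the liability scale with
    correction for case enrichment; population attributable risk fractions
    with parametric-bootstrap confidence intervals; genotype-specific
    absolute risk under Hardy-Weinberg equilibrium constrained to a stated
    population prevalence; and an exact liability-threshold simulator for
    ascertained case-control cohorts that works at prevalences as low as
    ~1 per 100,000.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
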