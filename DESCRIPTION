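Package: exoburden
Title: Exome-Wide Rare-Variant Burden Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the total number of rare,
    protein-altering exome variants an individual carries (their mutation
    load) predicts a quantitative trait, with cognitive ability as the
    motivating phenotype. Provides a synthetic exome-array cohort
    generator with known ground-truth effects, PLINK binary genotype
    input/output, the standard exome-chip second-stage quality-control
    cascade (haploid heterozygous calls, monomorphic variants, call-rate
    filters), per-individual rare-allele burden scoring by functional
    class and minor-allele-frequency threshold, a principal-component
    fluid cognitive factor, and covariate-adjusted linear association
    models with a sensitivity grid and Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
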