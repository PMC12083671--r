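Package: zknock
Title: Summary-Statistic Knockoff Inference for GWAS with Related Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knockoff-based false discovery rate control for genome-wide
    association studies using only marginal Z-scores and a linkage
    disequilibrium (LD) reference panel. Generates multiple Gaussian knockoff
    copies of the Z-score vector per LD block, applies the multiple-knockoff
    (kappa, tau) selection filter at a target FDR, and accepts Z-scores from
    (mixed-model) score tests or from an overlap-aware meta-analysis of
    several studies. Includes linear and logistic (mixed-model) single-variant
    association tests with a block-kinship fast path, a pedigree gene-dropping
    simulation engine with case-control family ascertainment schemes, and a
    replicated benchmark harness estimating empirical FDR and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
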