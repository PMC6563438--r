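Package: agroeaa
Title: Environment Association Analysis for Crop Landraces from Daily Climate Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for genotype-environment
    association in inbred crop landrace collections. Computes an agroclimatic
    variable catalogue (potential vernalization under a diurnal sine model,
    late-frost return periods, frost days, thermal amplitude, climatic water
    balance) from daily weather series; generates spatially correlated dummy
    variables by unconditional Gaussian simulation to build empirical null
    distributions; performs allele-frequency/environment association via
    hierarchical Bayes factors under null and population-covariance models,
    Spearman correlations, consensus and dummy-based thresholds, and
    latent-factor association with Fisher-Stouffer run combination and FDR
    control; scans population differentiation (expected heterozygosity,
    haploid Weir-Cockerham Fst, covariance-aware XtX with simulated-neutral
    calibration, structure-corrected LD) in centimorgan sliding windows; and
    partitions variance in group membership with redundancy analysis,
    permutation tests and dummy-stopped forward selection. A seeded
    synthetic-data module with known truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
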