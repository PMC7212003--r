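Package: uasqtl
Title: Functional Growth Modeling and Temporal QTL Mapping for
    Drone-Derived Plant Height
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for temporal mapping of
    quantitative trait loci (QTL) from multi-flight unoccupied aerial
    system (UAS) canopy-height phenotypes in recombinant inbred line
    (RIL) populations. Includes a synthetic-data generator for RIL
    genotypes and randomized complete block field trials, point-cloud
    canopy percentile extraction, per-flight REML variance components
    and BLUPs, three-parameter Weibull sigmoid growth-curve fitting
    with daily height imputation, Kosambi linkage-map construction
    with genotype cleaning and marker binning, inclusive composite
    interval mapping (ICIM-ADD) genome scans at a 1 cM step, and
    clustering of day-by-day QTL calls into temporal QTL with effect
    trajectories and sign-switch detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
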