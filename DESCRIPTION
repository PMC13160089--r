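Package: LoopFRiP
Title: Loop-Extrusion Simulation and Background Correction for ChIP-seq FRiP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cohesin positioning at CTCF sites with the
    fraction-of-reads-in-peaks (FRiP) statistic. Provides a stochastic 1D
    loop-extrusion simulator with dynamic CTCF barriers that yields in-silico
    ChIP profiles and simulated FRiP as a function of cohesin and CTCF
    abundance; an equilibrium biochemical model of antibody-derived ChIP-seq
    background that rescales the background fraction under depletion; a
    spike-in based estimator of the background fraction from paired
    unperturbed/depleted experiments and a FRiP denoiser; interval-based FRiP
    and peak genome-fraction computation on BED/narrowPeak data; and seeded
    synthetic-data generators so every component is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'LoopFRiP-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'barrier-kinetics.R'
    'biochem-background.R'
    'extrusion-sim.R'
    'frip-intervals.R'
    'synth-fixtures.R'
    'spikein-correction.R'
    'run-command.R'
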