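Package: flexbench
Title: Benchmarking Protein Flexibility Predictions Against NMR and X-ray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess coarse-grained predictions of per-residue protein
    flexibility. Implements an anisotropic elastic-network normal-mode model on
    the C-alpha trace, extraction of experimental fluctuation profiles from
    multi-model NMR ensembles (iterative superposition and RMSF) and from
    crystallographic B-factors (Debye-Waller conversion), terminal-segment
    truncation and profile normalization, and benchmark-level statistics:
    Pearson and Spearman profile correlations, distribution skewness,
    histograms and cumulative counts, two-way ANOVA over prediction method and
    secondary-structure class, and pairwise significance matrices. A synthetic
    data generator produces C-alpha traces, Gaussian conformational ensembles
    with inflated terminal fluctuations, B-factor-encoded structures, and full
    benchmark sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    e1071,
    MASS,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
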