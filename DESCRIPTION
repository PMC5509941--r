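Package: musemap
Title: Encoding and Decoding of Music Features from Multivoxel fMRI Patterns
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for multivoxel pattern analysis of fMRI
    responses to short music stimuli. Builds schematic melody features
    (absolute and relative pitch-class indicator matrices on a metrical grid)
    and acoustic chromagram features, reduces them by singular-value
    decomposition, estimates per-stimulus voxel response patterns with a
    double-gamma GLM, decodes song identity and genre with linear support
    vector machines under leakage-safe cross-validation, fits spherical
    searchlight ridge-regression stimulus-encoding models scored by
    correlation-error probability, and performs group-level inference with
    randomized-target null models, subject-wise bootstrap resampling, and
    FWE-corrected cluster reporting. Ships a synthetic-data generator with
    planted ground truth for end-to-end parameter- and region-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
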