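# musemap

Multivoxel pattern analysis of fMRI responses to short music clips: does a
local group of voxels carry information about *which song* is playing, its
*genre*, and the *melodic and harmonic content* of the stimulus?

`musemap` implements the full analysis stack for this question at desk
scale, exercisable end-to-end on synthetic data with planted ground truth:

- **Music features.** Melody transcriptions on a 16th-note metrical grid
  become binary 60 × 12 pitch-class indicator matrices at 0.1 s frames
  (absolute pitch, or transposed to C for relative pitch); audio becomes a
  continuous chromagram of the same shape. Each feature set is reduced by
  SVD (minimal *k* with ≥ 95% training variance) and each stimulus is the
  stacked vector of its 60 projected frame vectors.
- **GLM responses.** Per-voxel OLS with a canonical double-gamma HRF
  (`h(t) = g(t; 6, 1) − g(t; 16, 1)/6`) turns each run into one beta per
  stimulus per run.
- **Decoding.** Linear SVMs (`C = 1 / mean‖x‖₂`, one-vs-one) classify song
  (25-way, leave-run-out, chance 4%) and genre (5-way,
  leave-one-stimulus-per-genre-out, chance 20%) after one-way-ANOVA voxel
  selection computed only on two reserved runs; z-scoring is folded into the
  cross-validation. Model confusions are compared to behavioral confusions
  by Spearman correlation over the strictly-upper-triangle entries.
- **Encoding searchlight.** In every radius-3 voxel sphere (≤ 123 members),
  ridge regression predicts the multivoxel pattern from the stimulus feature
  vector; accuracy is the correlation-error probability `1 − p` of the
  Pearson correlation between predicted and observed patterns, averaged
  over 5 held-out stimuli × 8 runs × 10 repetitions = 400 tests per sphere.
  Centers may be scattered on a 3-voxel lattice (27× fewer spheres).
- **Group inference.** Randomized-target null models per subject,
  subject-wise bootstrap of group-mean null maps, voxel-wise `p < 0.001`
  thresholding, and FWE cluster-size correction (`p < 0.05`) with cluster
  tables (size, max, mean, std, center of mass, `p_cluster`).
- **Synthetic data.** A generator with known ground truth: genre-structured
  melodies, polyphonic chromagrams with RMS equalization and onset ramps,
  brains with planted feature-encoding regions (`amplitude = W · feature`),
  HRF-convolved event designs with inter-trial gaps in {4, 6, 8} s, and a
  configurable behavioral confusion matrix.

## Worked example

Simulate one subject with three planted regions (absolute-pitch melody,
relative-pitch melody, chromagram), estimate betas, and decode:

```r
library(musemap)

subj <- simulate_subject(rng_seed = 4, shape = c(8, 8, 6), snr = 2,
                         epi_format = "matrix")
bp   <- fit_betas(subj$session)

dec <- run_decoding(bp, target = "song", k = 200)
dec$accuracy
#> [1] 1

sl <- run_searchlight(bp, subj$features$melody_rel, repetitions = 10,
                      rng_seed = 7, offset = c(0, 0, 0))
sl$n_tests
#> [1] 400
```

Song decoding at SNR 2 is perfect (chance is 1/25 = 4%): the planted
linear code `W · feature` is exactly what the SVM recovers from held-out
runs. Each searchlight sphere was scored on 400 ridge-regression tests;
`sl$center_values` holds the per-sphere correlation-error probabilities
(≈ 0.5 in background noise, → 1 inside planted regions).

On signal-free data the decoders calibrate to chance:

```r
cal <- chance_calibration(n_seeds = 10, rng_seed = 1)
round(100 * colMeans(cal[, c("song", "genre")]), 1)
#>  song genre
#>   4.1  22.0
```

A full pipeline run (simulate → features → GLM → decode → searchlight)
with provenance and result files:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "musemap"))
```

## Layout

- `R/` — features, GLM, decoding, searchlight, group stats, synthetic data,
  NIfTI/WAV/ABC/events I/O, pipeline orchestration
- `src/` — Rcpp kernels: linear-SVM dual coordinate descent, sphere scoring,
  bootstrap accumulation, cluster-size nulls
- `tests/testthat/` — unit, property, and acceptance tests
  (`test-acceptance.R` implements the desk-scale acceptance criteria)
- `vignettes/methods.Rmd` — the model, its assumptions, parameter choices,
  and known limitations
- `inst/cli/musemap.R` — command-line entry point
  (`simulate | features | decode | searchlight | run-all`)
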