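---
title: "Methods: encoding and decoding music features from multivoxel fMRI patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding and decoding music features from multivoxel fMRI patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(musemap)
```

## The problem

Listening to music engages parallel representations: the acoustic surface
(spectral energy per pitch class), schematic structure (which scale degrees
sound when, in absolute or relative pitch), and categorical knowledge
(genre). `musemap` implements a complete desk-scale pipeline for asking
where and how such representations are encoded in multivoxel fMRI patterns:

1. **Stimulus features.** Monophonic melody transcriptions on a 16th-note
   metrical grid become binary 60 x 12 pitch-class indicator matrices at
   0.1 s frames, in the original key (`melody_abs`) or transposed so the
   tonic maps to C (`melody_rel`); audio (or the synthetic generator)
   yields continuous nonnegative chromagrams of the same shape. Each
   feature set is reduced by SVD, keeping the smallest number of components
   explaining at least 95% of training variance, and each stimulus becomes a
   `60*k` vector by stacking its projected frame vectors in temporal order.
2. **Voxel responses.** A per-voxel GLM with a canonical double-gamma HRF
   turns each run's time series into one response estimate (beta) per
   stimulus per run.
3. **Decoding (Analysis 1).** Within-subject linear SVMs classify song
   (25-way, leave-run-out) and genre (5-way, leave-one-stimulus-per-genre
   out), after one-way ANOVA voxel selection computed only on two reserved
   runs; z-scoring is folded into cross-validation. Model confusions can be
   compared with a behavioral confusion matrix by Spearman correlation over
   the strictly-upper-triangle entries.
4. **Encoding searchlight (Analysis 2).** In every radius-3 voxel sphere, a
   ridge regression predicts multivoxel patterns from stimulus feature
   vectors; prediction accuracy is the correlation-error probability
   `1 - p` of the Pearson correlation between predicted and observed
   pattern. Balanced cross-validation holds out one random stimulus per
   genre (all runs), repeated 10 times: 5 x 8 x 10 = 400 tests per sphere.
5. **Group statistics.** Randomized-target null models (shuffling which
   feature vector labels which stimulus) are rerun through the searchlight
   per subject; group-mean null maps are built by subject-wise bootstrap;
   voxels above the per-voxel `1 - 0.001` null quantile form clusters
   (face connectivity) that are FWE-corrected against the null distribution
   of maximum cluster size (`p < 0.05`), reported with size, accuracy
   statistics, and center of mass.

Everything runs end-to-end on synthetic data with planted ground truth, so
parameter recovery and region recovery are testable.

## The synthetic world

The generator emulates the structure of a 7T music-listening session: 25
six-second stimuli, five per genre, each run presenting all 25 once with
inter-trial gaps drawn from {4, 6, 8} s; 8 runs of 153 volumes at TR 2 s.
Stimulus keys follow the published stimulus table; tempos are genre-typical
values chosen once (Ambient 70, Country 100, Heavy Metal 140, Rock'n'Roll
160, Symphonic 90 bpm -- all multiples of 2.5 bpm so a 6 s clip spans an
integer number of 16th notes).

**Melodies** are bounded random walks on scale degrees with per-genre note
density, duration distribution, and scale-degree weights, so within-genre
melodies are statistically more similar than between-genre (property-tested
on duration-weighted pitch-class histograms). **Chromagrams** are
synthesized directly (no audio rendering): melody indicator energy plus
triad/bass energy on a seeded I-IV-V progression, multiplicative amplitude
modulation, additive half-normal noise, a 50 ms quarter-sine onset/offset
ramp, and RMS equalization so total energy is identical across stimuli.
**Brains** are voxel grids with planted regions; each region has a feature
kind and a Gaussian readout matrix `W`, and a voxel's response amplitude to
stimulus *s* is its row of `W %*% feature_vector(s)`. Time series are the
HRF-convolved event regressors scaled by those amplitudes plus white noise;
SNR is defined per voxel as signal sd / noise sd (default 1 in planted
regions; background voxels are unit-variance noise). The same HRF code
builds the simulator and the analysis design matrix, so the noise-free
forward/inverse round trip recovers planted amplitudes to ~1e-15 relative
error.

What the generator deliberately does **not** model: scanner drift, motion,
physiological noise, spatial autocorrelation, hemodynamic nonlinearity, and
second-order counterbalancing of genre order (uniform random permutations
per run instead). A green recovery test therefore establishes the
correctness of the estimators and inference machinery, not robustness to
real-data artifacts.

One consequence worth stating plainly: in this forward model the genre
decoder has almost no generalization signal. Genre structure enters only
through feature-vector similarity, and stacked frame-wise vectors of
different melodies are nearly orthogonal even within a genre (shared
statistics, different timing). Song decoding -- the same stimulus in held-out
runs -- is strongly decodable at high SNR, and the 5-way genre decoder is
used for chance calibration; no synthetic claim is made about above-chance
genre decoding.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `tr` / `volumes_per_run` / `n_runs` | 2 / 153 / 8 | s, count | session geometry of the target experiment |
| HRF | peak 6 s, undershoot 16 s, dispersions 1, ratio 1/6 | s | canonical double-gamma values; the source names the family only |
| `min_variance` | 0.95 | fraction | SVD retention criterion; k is minimal |
| `k` (ANOVA selection) | 5000 | voxels | matches the reference analysis; tests use smaller grids and smaller k |
| SVM `C` | `1 / mean(l2 norm of training rows)` | -- | "C scaled according to the norm of the data"; the exact statistic is unstated, so the rule is explicit and configurable (`C0`, `C`) |
| `radius` / `scatter_step` | 3 / 3 | voxels | sphere geometry (max 123 members) and 27x compute saving |
| `repetitions` | 10 | -- | 400 tests per sphere |
| ridge `lambda` | 1.0 | -- | unstated in the source; on z-scored data a unit penalty is a neutral default, configurable everywhere |
| `voxel_p` / `cluster_p` | 0.001 / 0.05 | -- | voxel-wise and FWE cluster thresholds |
| `n_null` / `n_bootstrap` | 20 / 10,000 | -- | desk-scale defaults (reference scale: 100 / 100,000), plain arguments |

## Numerical and design choices

- **Resampling rule.** Metrical grid to 0.1 s frames takes the slot active
  at the frame center: preserves binarity, introduces no interpolation
  values, and conserves the sounding pitch-class set.
- **Transposition.** Columns rotate by the tonic pitch class; minor keys
  transpose by tonic, ignoring mode.
- **SVD.** Frames are mean-centered with the training mean; basis sign is
  fixed by making the largest-magnitude loading positive; the basis is refit
  inside every cross-validation training fold; test stimuli are never read
  during fitting (asserted by a mutation test).
- **GLM.** OLS per voxel, no prewhitening; constant + linear trend nuisance
  per run; rank-deficient designs are an error, not silently regularized.
- **Z-scoring.** Always from training cells only; zero-variance voxels get
  an epsilon floor and a flag. The searchlight variant z-scores per run
  across training stimuli, removing run-level offsets.
- **Ridge.** One shared penalty across voxels; unpenalized intercept via
  centering (as `lambda` grows, predictions shrink to the training mean
  pattern); dual (kernel) form when features outnumber training rows --
  algebraically identical, property-tested against the primal and the
  closed form.
- **Correlation-error probability.** Two-sided t-test p of the Pearson r
  over sphere members (the source does not state sidedness); constant
  patterns score 0 and are flagged. Scores of the 400 tests are computed
  per (stimulus, run) pattern and averaged (the main metric ambiguity; the
  pooled-vector alternative is noted but not implemented).
- **Cluster inference.** Empirical p values use the `(r+1)/(B+1)`
  convention; connectivity defaults to 6 (faces); the center of mass is the
  unweighted mean of member voxel coordinates, converted through the affine
  for reporting.
- **Scattering and localization.** Scattered maps are completed by
  nearest-computed-center fill. At the scale of 2-voxel slabs the random
  scatter lattice is generically one-sided with respect to a slab, which can
  pull a cluster's center of mass ~1 voxel outside it; the region-recovery
  acceptance test therefore uses exhaustive centers (`scatter_step = 1`),
  the base form of the method. Scattering remains the default for maps,
  where the 27x saving matters and per-voxel localization is not read off a
  2-voxel structure.
- **What the recovery test counts as a false positive.** A searchlight map
  value at voxel *v* derives from the sphere around *v*, so signal-driven
  detections legitimately extend up to one radius outside a planted region.
  The region-recovery test plants laterally bounded slabs (12 x 12 x 2 in a
  24^3 grid) so that regions dilated by the sphere radius still leave a
  majority of genuine background, requires the matching-kind cluster's
  center of mass inside its region, and flags as a false positive only a
  significant cluster with zero overlap with the dilated regions. Clusters
  of one kind's map overlapping another kind's region are expected: the
  synthetic chromagram embeds the melody, so the feature sets are
  correlated, exactly as acoustic and schematic features are in real music.
- **Null models.** Each null permutes the stimulus-to-feature assignment
  and reruns the searchlight with the same scatter offset and shared
  cross-validation draws (the permutation is the randomness); the identity
  permutation reproduces the true map exactly. Group inference requires one
  center lattice across subjects, so the offset is fixed per analysis.

## Known limitations

- Genre decoding on synthetic data is a calibration tool, not a
  demonstration (see above).
- The chromagram extractor is a magnitude-STFT pitch-class folding
  (A4 = 440 Hz); the published analysis used an external toolkit whose
  algorithm is unspecified, so only the invariants (nonnegativity,
  pitch-class rotation under transposition, octave folding) are contractual.
- The bootstrap stores the full `B x centers` matrix; at reference scale
  (100,000 x whole-brain) this would need a streaming implementation.
- Real-data headline numbers (21.1% song decoding at HG, Table-2 cluster
  inventory, etc.) require the public 7T dataset and are out of desk-scale
  scope; nothing in the package asserts them.
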