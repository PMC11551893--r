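---
title: "Decoding and representational geometry of sequence preparation and production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and representational geometry of sequence preparation and production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmvpa)
```

## The problem

In motor sequence experiments, participants prepare and then produce short
finger-press sequences that cross two factors: the serial **order** of the
presses and the **timing** (inter-press interval structure) they are paired
with. A first-level GLM yields one activation pattern ("beta weights" over
voxels) per condition per imaging run: with 2 orders x 2 timings x 2 phases
(preparation, production) and 6 runs, 48 patterns per subject and region.
Two questions drive the analyses in this package:

1. **What is represented where?** Does a region carry information about
   sequence order, about timing, or about their non-additive integration —
   and does it do so already during preparation, before any movement?
2. **Does the representation change between phases?** Are production patterns
   merely scaled-up preparation patterns, or does the code switch between
   planning and execution?

Because these analyses are typically validated on data that cannot be
redistributed, the package ships a generative simulator that reproduces the
statistical structure of such datasets, and every claim the package makes is
demonstrated on simulated data with known ground truth.

## The generative model

`simulate_subject_patterns()` draws the pattern for order *i*, timing *j*,
run *k* as

    y_ijk = s_i + t_j + i_ij + r_k + e_ijk

where each component is an independent zero-mean normal vector over voxels:
`s` (2 order patterns), `t` (2 timing patterns), `i` (4 integrated patterns,
one per order-by-timing cell), `r` (run effects, one per run, shared by both
phases of a run since both are estimated from the same acquisition), and
fresh white noise `e` per observation. Production patterns either re-use the
preparation components (`switch = FALSE`, optionally scaled by `prod_scale`)
or are drawn afresh (`switch = TRUE`), and receive a uniform `phase_offset`.

Defaults and why:

* `n_voxels = 160`, `n_runs = 6`, `n_subjects = 24` — the design scale of a
  typical subcortical ROI study with 160-voxel searchlights.
* `var_s = var_t = var_i = 1` — the three representational components share
  one variance; only their ratio to the noise matters for every downstream
  statistic, so the scale is arbitrary.
* `var_r = 1` — run effects of the same order of magnitude as the signal,
  a realistic nuisance level for session-wise beta estimates.
* `phase_offset = 5` (five component SDs) — production raises overall
  activity massively relative to pattern differences, so the first principal
  component of the joint geometry is a phase axis. This mimics the dominant
  activity-level difference seen in real planning/execution data.
* Noise can be given as target per-phase signal-to-noise ratios
  (`snr_prep`, `snr_prod`), SNR being summed signal component variance over
  noise variance. When both are given, `prod_scale = snr_prod / snr_prep`,
  so the signal scale factor between phases equals the SNR ratio.

Where we quote an "ROI-like" SNR below we use 0.5: fMRI pattern component
variance is typically well below the trial-to-trial noise variance, and 0.5
gives single-subject decoding accuracies in the realistic 0.6–0.9 band
rather than at ceiling.

**What the simulator does not emulate:** spatial noise correlations,
hemodynamic temporal structure, motion artifacts, between-subject anatomical
variability, and trial-level variability below the condition-by-run
granularity. Passing tests therefore demonstrate the *statistical logic* of
the pipeline — calibration, independence, unbiasedness, localization — not
robustness to every physiological nuisance of real data.

## Factorized decoding

`decode_sequences()` implements three linear discriminant (LDA) decoders:

* **order** — trained on the two orders under one timing across all-but-one
  run, tested on the two orders under the *other* timing in the held-out
  run. Generalization across the paired timing is what certifies an
  order-specific code. All held-out-run x training-timing combinations give
  12 folds at 6 runs.
* **timing** — the mirror image, again 12 folds.
* **integrated** — per run and phase, the order-marginal and timing-marginal
  mean patterns are removed (`remove_marginal_means()`, the two-way
  interaction residual), and a 4-class LDA is cross-validated leave-one-run-
  out (6 folds).

The classifier (`train_lda()`) uses class means with one covariance pooled
across classes, shrunk toward its diagonal; with 10 training rows and 160
voxels the raw covariance is singular, so shrinkage defaults to an analytic
intensity estimated from the training residuals
(a Schafer–Strimmer-style target-diagonal estimator). Ties in the
discriminant break to the lowest class index — deterministic and
seed-independent. Correct guesses are pooled across folds and converted to a
single binomial z per subject and decoder (`accuracy_to_z()`); chance is 0.5
for order/timing and 0.25 for the integrated decoder.

A structural note on the integrated decoder: in a 2 x 2 design the two-way
interaction residual is one-dimensional — the residual patterns are
`+c, -c, -c, +c` over the four cells — so the four residual class means
collapse into two sign classes. Even with noiseless data the 4-class
accuracy is capped near 0.5. That is still twice the 0.25 chance level, and
the binomial z against chance remains the meaningful test statistic; but
integrated accuracies should never be expected near 1 and are not comparable
in magnitude to the order/timing accuracies.

## Representational geometry

`cross_phase_statistic()` chains the geometry pipeline:

1. **Noise covariance and prewhitening** (`estimate_noise_covariance()`):
   within-condition across-run residuals, covariance shrunk toward its
   diagonal, whitener = inverse principal square root. Prewhitening makes
   Euclidean distances on the patterns Mahalanobis distances with respect to
   the noise.
2. **Classical MDS** (`classical_mds()`): Torgerson scaling — eigendecompose
   the double-centered Gram matrix of run-averaged whitened condition means.
   Negative eigenvalues are clipped to zero with a warning (they can arise
   from cross-validated inputs; on Gram matrices of actual patterns they are
   numerical noise).
3. **Cross-phase distance** (`cross_phase_distance()`): per sequence, the
   Euclidean distance between its preparation and production coordinates on
   components 2–3. Component 1 is excluded because the phase activity offset
   dominates it; components 2–3 carry the sequence geometry.
4. **Normalization** (`normalize_cross_phase()`): the mean cross-phase
   distance is divided by the grand mean of the 6 within-preparation and 6
   within-production pairwise distances, computed on the same components so
   numerator and denominator share a subspace. The ratio is invariant to
   uniform rescaling of the patterns — a pure gain change from planning to
   execution does not move it. We pool both phases into one grand mean
   rather than normalizing each phase separately; with matched per-phase
   scales the two conventions agree in expectation.

**The crossnobis estimator and noise-covariance reuse.** `crossnobis_rdm()`
computes cross-validated Mahalanobis distances by pairing pattern
differences from independent runs, which makes the distance estimator
unbiased (zero expectation for identical conditions, negative values
possible). Unbiasedness, however, holds only if the whitening matrix is
independent of the differences: estimating the covariance from the same
runs' residuals couples the whitener to the noise and inflates the null
mean substantially. `crossnobis_rdm()` therefore
defaults to leave-pair-out estimation — the covariance used for run pair
(m, n) is estimated from the remaining runs — which restores exact
unbiasedness while still deriving the noise model from the patterns
themselves. A fixed covariance (e.g. from an independent noise estimate)
can be supplied instead; it needs at least 4 runs to leave a pair out.

**The no-switch baseline.** With noise, the cross-phase distance is
positively biased even when nothing changes between phases: noise pushes
preparation and production embeddings apart. The empirical statistic is
therefore tested (`test_against_baseline()`, one-sided t, Bonferroni over
regions, default 7) against the mean of `simulate_cross_phase_baseline()`
run with `switch = FALSE` and matched voxel count, run count, group size
and per-phase SNR. The matched `switch = TRUE` simulation provides the
reference level a full representational switch would produce.

## Searchlights and group maps

`define_searchlights()` builds one searchlight per in-mask voxel: in-mask
voxels sorted by physical distance (mm, using the voxel size — "6 mm" is a
native-space distance, not a voxel count) with lexicographic tie-breaking,
truncated at the first of the 160-voxel target or the 6 mm radius cap. At
2 mm isotropic resolution a 6 mm ball holds at most 123 lattice voxels, so
the radius cap binds under the defaults; both parameters are configurable,
and we treat the stated maximum radius as the hard constraint.
`run_searchlight()` assigns each searchlight's analysis value (typically a
decoding z) to its center voxel; failures become missing values rather than
aborting a map. `group_t_map()` performs the voxelwise one-sample t-test
across subjects (default threshold 3.48, the one-tailed p < 0.001 cutoff at
23 degrees of freedom) and reports 26-connected suprathreshold clusters
with extents — no random-field-theory cluster p-values, extents only.

## Numerical and design choices

* Covariance shrinkage target is the matrix's own diagonal everywhere
  (classifier and prewhitener), intensity configurable, "auto" analytic by
  default. Zero-variance voxels are floored with a warning.
* The SNR estimator (`estimate_snr()`) uses cross-run covariances of
  condition patterns for the signal (run effects and noise cancel across
  runs) and the two-way (condition + run) residual variance for the noise,
  so it is calibrated against the generative model: ratios of 0.5 are
  recovered within a few percent on average.
* One row per condition per run — the granularity of GLM beta estimates; no
  trial-level rows.
* Problem sizes in the test suite are the package's own choices: the null
  calibration runs 1,000 groups of 12 subjects at 30 voxels (the null z
  distribution does not depend on voxel count), independence and switch
  checks run at the full 160 voxels, and searchlight localization uses an
  8 x 8 x 8 volume with a 160-voxel signal box and 3 mm searchlights.

## Known limitations

* The integrated decoder's 2 x 2 interaction ceiling (above) means its
  accuracy scale is not comparable to the factorized decoders'.
* White noise per observation: no spatial or temporal noise correlations, so
  prewhitening is exercised mainly through shrinkage and simulation-injected
  covariance structure in tests, not through physiologically realistic
  correlation patterns.
* Cluster inference is descriptive (extent lists); no family-wise-error
  correction over space is computed.
* The pipeline's group analyses assume one dataset per subject and a
  complete 2 x 2 x phase x run design; incomplete designs are rejected
  rather than imputed.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_voxels = 160, snr_prep = 0.5, snr_prod = 0.5, seed = 42)
ds <- simulate_subject_patterns(cfg)
decode_sequences(ds, "order", "preparation")$z
cross_phase_statistic(ds)

report <- run_full_analysis(pipeline_config(
  simulation = sim_config(n_voxels = 60, snr_prep = 0.5, snr_prod = 0.5,
                          n_subjects = 12),
  n_baseline_sims = 5, output_dir = tempfile(), seed = 7))
report$geometry
```
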