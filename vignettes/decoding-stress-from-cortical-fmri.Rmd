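---
title: "Decoding self-reported stress from cortical fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding self-reported stress from cortical fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A subject watches alternating calming and stress-inducing scenes inside an
MRI scanner and reports a subjective stress level from 1 (least) to 8 (most
stressful) every 15 s. At a repetition time (TR) of 1.5 s, one report covers
10 brain volumes ("frames"). The goal is a per-subject decoder that maps
whole-cortex BOLD activity onto the reported 8-level ordinal state — the
kind of decoder a real-time neurofeedback loop needs. `cortexstress`
implements the full chain: a synthetic BOLD generator with a known ordinal
ground truth, cortical feature extraction, temporal preprocessing,
SVM/SVR/MLP decoding with root-mean-square error (RMSE) and accuracy over
repeated splits, and permutation-based significance testing.

Because RMSE is computed on ordinal labels, it penalizes distant confusions
(predicting 7 for a reported 2) much more than adjacent ones; exact-match
accuracy ignores that distinction. A useful decoder in this setting shows
high accuracy *and* low RMSE, which requires its errors to be predominantly
±1 level.

## Pipeline

1. **Sample** each 4D volume onto the gray–white surface mesh (trilinear
   interpolation at each vertex's voxel coordinate; `sample_volume_to_surface`).
2. **Smooth along the manifold** (`surface_smooth`): iterative graph
   diffusion restricted to mesh edges, so smoothing follows the folded
   cortical sheet rather than cutting across sulci.
3. **Downsample into patches** (`build_patch_partition`, `patch_features`):
   farthest-point sampling of K patch centers under graph-geodesic distance,
   nearest-center assignment, and per-patch averaging. The default
   K = 5100 gives the low-dimensional whole-cortex feature set.
4. **Temporal preprocessing** (`preprocess_subject_features`), per run and
   in this fixed order: optional nuisance regression (6 motion traces and an
   HRF-convolved button-press stick, plus an intercept; feature means are
   restored afterwards so later normalization stays well-defined), optional
   discrete-cosine high-pass filtering, optional Wiener deconvolution of the
   hemodynamic delay, then percent-signal-change normalization. Every
   optional step is an exact no-op when disabled; disabling all three is the
   base case of the four-row preprocessing ablation (`run_ablation`).
5. **Block averaging** (`block_average`): within each report's 10-frame
   window, the last `floor(10/BS)*BS` frames are kept and averaged in
   non-overlapping blocks of BS ∈ {3, 4, 5} frames; each block sample
   inherits the report's label. The *earliest* frames are the ones dropped,
   because they sit closest to the previous clip and carry the most
   hemodynamic contamination. Blocks are non-overlapping (no sliding
   window).
6. **Decoding** (`run_experiment`): 25 iterations; each iteration splits at
   the *report* level (all block samples of a 15 s report stay on one side),
   stratified by level, ranks features by one-way ANOVA F on the training
   rows only, standardizes with training statistics only, trains the
   decoder, and scores the held-out samples.
7. **Significance** (`permutation_test`): labels are permuted at the report
   level and the full experiment is re-run per permutation; the add-one
   p-value is `(1 + #{null ≤ observed}) / (1 + n_permutations)`.

## The synthetic generator

`simulate_bold` emulates the acquisition this framework targets: 2 mm cubic
voxels, TR 1.5 s, 8-min runs of interleaved stress clips (levels 2–8,
60/90 s) and calm clips (level 1, 30/60 s), a report every 15 s, 2 sessions
of 5 runs (smaller layouts are used for fast demonstrations). Key modeling
choices:

* **Ordinal spatial encoding.** Each level l has a smooth spatial map
  β_l over gray-matter voxels (Gaussian random fields, FWHM
  `pattern_smoothness_mm`, default 6 mm). Maps form a level-wise chain with
  `cor(β_l, β_{l+1})` held *exactly* at `ordinal_overlap` (default 0.6) by
  empirical orthogonalization, so levels at ordinal distance d correlate
  ≈ 0.6^d: neighboring levels are confusable, distant ones are not. This is
  what makes RMSE a meaningful ordinal metric for the decoders.
* **Emotional inertia.** The subject's internal stress state does not jump
  with the clip cut; it steps one level toward the clip's target every
  `ramp_frames_per_level` frames (default 2, i.e. 3 s per level). Each
  level's neural activation remains a boxcar (the periods where the state
  occupies that level), convolved with a canonical double-gamma HRF.
  Without this, a calm→level-8 cut would produce block samples whose label
  says 8 while the lagged hemodynamic signal still encodes 1 — irreducible
  7-level errors that no decoder can fix, a regime in which ~88% accuracy
  coexists with RMSE near 1.5. With the ramp, errors concentrate at ±1–2
  levels and RMSE lands in the 0.5–0.8 range at ~90% accuracy.
* **Report semantics.** The simulated self-report for a window is the level
  whose HRF-convolved response *dominates* that window — the label is
  representative of the stress response over the preceding 10 frames, which
  is exactly how the reports are treated downstream.
* **Noise.** AR(1) voxel noise (stationary SD `noise_sd`·baseline, lag-1
  coefficient 0.3), plus a per-run slow drift (random per-voxel mix of a
  linear term and the DCT k=1 half-cosine, amplitude 1% of baseline). The
  half-cosine is deliberately the DCT-II basis shape so the high-pass step
  removes it exactly. Optional motion and button-press artifacts are driven
  by the same regressors the nuisance step removes, giving the ablation a
  testable target.
* **Determinism.** All randomness flows through R's Mersenne-Twister
  (inversion normals, rejection sampling — the R ≥ 3.6 defaults), locally
  seeded and restored, so identical seeds give bit-identical outputs. The
  per-level spatial maps depend only on the base seed and are therefore
  shared across sessions (they are the subject's stable encoding), while
  noise, drift and artifacts use a session-offset stream.

What the generator does **not** emulate: cardiac/respiratory physiological
noise, image motion itself (only motion-driven intensity artifacts),
susceptibility distortion, multi-subject anatomical variability, or any
structure in *which* levels follow which (the stress-level sequence is
uniform-random). Passing tests on this generator show the pipeline's
machinery is correct and well-calibrated — not that real clinical data
would decode at these error rates.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `effect_amplitude` | 0.03 | fractional BOLD change per unit activation (~3% at plateau) |
| `noise_sd` | 0.02 | fractional SD of AR(1) voxel noise |
| `ordinal_overlap` | 0.6 | correlation of adjacent-level spatial maps |
| `ramp_frames_per_level` | 2 | frames per one-level step of the internal state |
| `fwhm_mm` (smoothing) | 6 | manifold smoothing extent |
| `K_base` | 5100 | patch count (feature dimensionality) |
| `K_sub` | 1600/2400/4700 | ANOVA-F-selected feature counts |
| `BS` | 3/4/5 | block size (frames averaged per sample) |
| `cutoff_hz` | 0.01 | DCT high-pass cutoff |
| `snr_param` | 100 | Wiener regularization |
| `test_fraction` | 0.2 | held-out report fraction per iteration |
| `n_iterations` | 25 | randomized splits per experiment |
| `n_permutations` | 25 | label permutations for the null |

## Numerical choices

* **Smoothing calibration.** One diffusion step
  `x ← (1−λ)x + λPx` (P: row-normalized Gaussian edge weights,
  σ_edge = mean edge length h; λ = 0.5) spreads variance by ≈ λh² along
  the mesh, so the iteration count for a requested FWHM is
  `ceiling(σ² / (λh²))` with σ = FWHM/√(8 ln 2). FWHM 0 is the exact
  identity. The operator preserves constants, obeys the maximum principle,
  and never increases per-frame variance.
* **Farthest-point ties** go to the lowest vertex id; nearest-center
  assignment ties go to the earlier (lower-id) patch center.
* **ANOVA-F ties** rank the lower feature id first; a feature with zero
  within-class variance but non-zero between-class variance gets F = ∞
  (ranked first); a feature constant across all samples gets F = 0.
* **Degenerate inputs.** Percent signal change refuses zero-mean features by
  name; nuisance regression prunes collinear columns by pivoted QR at
  relative tolerance 1e-10 and errors if still rank-deficient; splits refuse
  to starve the test side, keep ≥ 2 training reports per level, and send
  single-report levels to training with a warning.
* **SVR accuracy rounding**: predictions are clipped to [1, 8]; RMSE uses
  them unrounded (regression framing), accuracy rounds halves away from
  zero first.
* **Wilcoxon convention**: when every paired difference is zero the
  comparison returns p = 1.
* **Hyperparameter defaults**: RBF kernel with cost 1 and γ = 1/p for
  SVM/SVR (ε = 0.1 for SVR); the MLP uses two hidden layers (32, 16),
  ReLU, softmax over the 8 levels, full-batch Adam (learning rate 1e-3,
  weight decay 1e-4, 200 epochs), with seed-deterministic initialization.
  All are exposed in `experiment_config`.

## Design decisions in open territory

* The exact blurring kernel and the construction of the ~5100-feature set
  are implemented as graph-diffusion smoothing plus farthest-point patch
  averaging — a faithful reading of "blur and downsample along the
  gray-matter ribbon" — with both parameterized.
* Feature subselection uses training-only ANOVA F ranking: simple,
  leakage-safe, and consistent with per-model feature-count optimization
  (`optimize_feature_count`, ties toward the larger count).
* Splitting, feature ranking and standardization all operate at or within
  the training side only; a canary test (a feature encoding *test* labels
  with noise on train) verifies that held-out RMSE does not improve.
* Permutation is at the report level, preserving the block structure the
  split respects; sample-level permutation would make the null
  anti-conservative on autocorrelated data. Permutations are unrestricted
  across runs and sessions.
* The null-calibration check (zero effect amplitude → permutation p above
  0.05, observed mean inside the null's central 95% band) is run on
  high-pass-filtered features. This is not a convenience: the simulated
  scanner drift is a genuine non-stimulus confound shared between
  temporally clustered labels and slowly varying features, so on unfiltered
  features the decoder *honestly* finds label structure at zero effect —
  removing the drift with the framework's own filter is the correct
  experiment. Even then p concentrates mildly toward 1, because the true
  label sequence is temporally clustered while permuted ones are
  exchangeable; the test errs conservative.
* The empirical null RMSE is bounded below by the constant-predictor floor
  √5.25 ≈ 2.29 *for balanced labels*; the generator's sessions are
  calm-heavy (level 1 occupies the inter-stress rests), so null means on
  simulated sessions typically sit higher (≈3–4) — the analytic floors are
  verified as closed forms on balanced labels.

## Problem sizes used by the tests and the acceptance script

The test suite exercises the full pipeline at reduced scale: icosphere
k = 2–3 meshes (162–642 vertices), 120–600 patches, 2–4 runs of 4–8 min,
and reduced iteration/permutation counts; geometric and temporal operator
checks run against dense oracles at 162 vertices. The acceptance script
runs the demonstration subject at full feature scale — icosphere k = 5
(10242 vertices), 5100 patches, top 4700 features, 2 sessions × 2 runs of
8 min, 25 split iterations and 25 permutations (null replicates use 5
inner iterations each; every null point is a mean over those splits).
A representative acceptance run prints mean RMSE ≈ 0.57 (SD ≈ 0.21),
accuracy ≈ 91%, permutation p = 1/26 with disjoint observed and null
distributions.

## Known limitations

* The generator's spherical mesh has none of the geometric anisotropy of a
  real cortical surface; smoothing and patching behave more uniformly than
  they would on real anatomy.
* Volumes and mesh are assumed co-registered; there is no registration,
  segmentation or surface reconstruction here.
* The MLP is a compact two-hidden-layer network trained full-batch; it is
  meant as the third decoder family, not as a tuned deep-learning model.
* Wiener deconvolution uses a circular convolution convention; run edges
  see wrap-around leakage (negligible for 320-frame runs with a 32 s
  kernel, but real for very short runs).
* Decoding latency, real-time streaming, and across-subject transfer are
  out of scope.
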