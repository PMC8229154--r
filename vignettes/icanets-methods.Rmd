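---
title: "Methods: group ICA network expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group ICA network expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icanets)
```

This vignette is the package's account of its statistical machinery: the
models and conventions each stage implements, the parameters that matter,
what the synthetic cohort generator does and does not emulate, and the
numerical choices made where the methods literature leaves the design
open.

## The pipeline model

The data model is the standard one for group spatial ICA of resting-state
BOLD. Subject $i$ contributes a voxels × time matrix $X_i$ over a common
mask. After per-voxel demeaning, subject-level PCA retains the top
temporal directions; the reductions are concatenated along time and a
second PCA whitens the pooled data to $K$ dimensions. In the whitened
space the generative assumption is $Z = A S$ with spatially independent,
super-Gaussian sources $S$ (rows are component maps, columns are voxels —
voxels are the statistical samples of spatial ICA). InfoMax estimates the
unmixing by natural-gradient ascent of the entropy of logistic-squashed
outputs, which matches super-Gaussian sources such as compact network
maps.

Stage by stage:

* **Model order.** $K$ is chosen by minimum description length in the
  Wax–Kailath form from the pooled eigenvalue spectrum, with the sample
  count $N$ set to the number of in-mask voxels — the observations behind
  the covariance whose spectrum is tested. `estimate_order_mdl()` itself
  is orientation-agnostic: callers supply eigenvalues and $N$. A flat
  spectrum returns 0 with a warning ("no detectable sources") rather than
  an error, since that is a legitimate answer about data with no
  structure.
* **Stability.** ICASSO reruns InfoMax `n_runs` times under bootstrap
  resampling of the sample (voxel) dimension, re-whitening each resample;
  pooled estimates are clustered by average-linkage agglomeration on
  $1 - |r|$ cut at exactly $K$ clusters. Each cluster reports
  $I_q$ = mean intra-cluster similarity (self-pairs excluded) − mean
  similarity to outside estimates, and is represented by its centrotype
  (the member with maximal total intra-cluster similarity). Components are
  renumbered in decreasing $I_q$.
* **QC.** Retention applies, in order: $I_q \ge$ `iq_min` (default 0.8),
  not user-labeled artifact, and at least `min_voxels` (50) voxels at
  $|z| \ge$ `cutoff` (1.0) on the z-scored map — exactly 50 passes, the
  rule is a strict "fewer than". Artifact identification is deliberately a
  user-supplied label file: such calls are expert visual judgments and not
  algorithmically reproducible. Low-frequency dominance (periodogram power
  below 0.1 Hz over total power, zero-frequency excluded) is computed and
  reported but excludes components only when `enforce_lowfreq` is set,
  mirroring how spectral QC is applied by inspection in practice.
* **Dual regression.** Stage 1 regresses each time point's volume on the
  voxel-demeaned group maps; stage 2 regresses each voxel's series on the
  variance-normalized stage-1 time courses, so stage-2 betas carry
  amplitude. Scaling a group map by $c$ scales its stage-1 time course by
  $1/c$ and leaves stage-2 maps invariant — a property the tests assert.
* **SSM scores.** For each component, the subjects × voxels matrix of
  back-reconstructed maps is row-centered (each subject's voxel mean
  removed), column-centered (mean profile removed), projected onto the
  group z-map, normalized by the topography's squared norm, and z-scored
  against the controls. The classical scaled-subprofile-model log
  transform is omitted: it presumes strictly positive images (PET), while
  ICA maps are signed; the subtractive double centering is retained, and
  with it the invariances — subject-wide constants and positive rescaling
  of a topography change no score.
* **Domain models.** Bidirectional stepwise regression in the mainstream
  statistics-package sense: the candidate with the smallest partial-F p
  enters while $p \le 0.05$; any included predictor with $p \ge 0.10$ is
  removed, worst first; iteration stops at a fixed point, with a cycle
  guard capped at $2p$ iterations that keeps the best-$R^2$ visited state.
  Confidence intervals are t-based with $n - k - 1$ degrees of freedom.
  An empty selection is reported as "model not generated" — a first-class
  outcome, not an error. Composite domain maps are the coefficient-weighted
  sums of the *group* z-maps, so they are linear in the coefficients and
  preserve coefficient signs.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `iq_min` | 0.8 | – | conventional stability floor for retaining a component |
| `cutoff`, `min_voxels` | 1.0, 50 | z, voxels | extent rule; strict "< 50 excludes" |
| `band_edge_hz` | 0.10 | Hz | resting-state fluctuations concentrate below 0.1 Hz |
| `alpha_enter`, `alpha_remove` | 0.05, 0.10 | – | the stepwise defaults of mainstream statistics packages |
| `n_runs` | 100 (`run_icasso`), 20 (pipeline) | runs | canonical ICASSO count; the pipeline default trades runs for runtime at desk scale |
| `subject_keep` | `1.5 K` | dims | common group-ICA practice for subject-level retention |
| `motion_threshold_mm` | 3.0 | mm | subjects with maximum displacement of 3 mm *or more* are excluded (inclusive reading) |

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. It
generates:

* **Sources**: Gaussian blobs (σ = 1.8 voxels, truncated at 3σ) at centers
  ≥ 5.5 voxels apart inside an ellipsoidal mask on a 20 × 20 × 10 grid.
  Each blob is centered over the mask and the set is symmetrically
  decorrelated before unit-norming. The decorrelation is a deliberate
  design choice: linear ICA assumes spatially uncorrelated sources, and
  raw positive blobs acquire mutual negative correlation once whitening
  removes their shared positive mean, which caps achievable recovery below
  what a correctness test should demand. Identifiability, not anatomical
  realism, is what downstream recovery tests need. Construction guarantees
  ≥ 50 voxels at $|z| \ge 1$ per source, so every true source survives the
  extent filter.
* **Time courses**: random-phase Fourier synthesis restricted to
  0.01–0.08 Hz at TR 2 s, standardized; so essentially all spectral power
  sits below the 0.1 Hz QC edge.
* **BOLD**: per subject, loading-scaled sources × time courses plus white
  Gaussian noise (sd 1 against a source amplitude of 30 on unit-norm
  maps); an AR(1) flag exists because real BOLD noise is autocorrelated,
  but white noise is the default study condition.
* **Loadings**: subject expression strengths, N(1, 0.3²), independent
  across components.
* **Domain scores**: for each MoCA domain (standard integer ranges:
  visuospatial/executive 0–5, naming 0–3, attention 0–6, language 0–3,
  abstraction 0–2, delayed recall 0–5, orientation 0–6), a sparse linear
  model on the loadings plus Gaussian residual, then rounding and clipping
  into range. The residual sd is calibrated so the *generating* model hits
  its target $R^2$ (attention: three components, mixed signs, target 0.6);
  the calibration subtracts the ~1/12 variance that integer rounding adds,
  and the test suite verifies the mean realized generating $R^2$ across
  100 cohorts is within ±0.05 of target. Delayed recall is generated with
  no planted coefficients, so a correct modeling stage reproduces the
  "model not generated" outcome class. Controls receive MMSE only,
  mirroring designs in which the detailed battery is administered to
  patients alone.

What the generator does **not** emulate: hemodynamic response shape, head
motion, scanner drift and artifacts, anatomical geometry, spatial noise
correlation, or between-component loading correlation. Passing recovery
tests therefore demonstrates the correctness of the estimators under the
stated model, not robustness to real-data pathologies.

## Numerical choices

* **InfoMax**: initial learning rate 0.015, annealed by 0.9 whenever the
  update direction reverses; mini-batch natural-gradient passes (block
  ≈ √(V/3), order reshuffled per pass) followed, once the batch phase
  converges, by deterministic full-batch polishing to the exact fixed
  point; tolerance 1e-6 on the maximum weight change, at most 500
  iterations; divergence restarts with a halved rate (up to 10 times)
  before a run is flagged non-converged. Non-convergence is a flagged
  result, not an exception; ICASSO drops such runs with a warning and
  errors only if more than half fail. The final unmixing is symmetrically
  orthogonalized — in whitened space the true unmixing is a rotation — so
  component estimates are exactly decorrelated, and duplicate runs yield
  $I_q = 1$ exactly. Map signs follow a skewness-positive convention,
  making reruns reproducible.
* **Degenerate inputs**: constant maps cannot be z-scored; constant time
  courses have no spectral ratio; duplicated group maps are refused with
  the collinear pair named; a perfect stepwise fit stops forward selection
  (nothing is left to explain, and p-values on zero residuals are
  numerical noise); score columns with zero control variance are errors.
* **Ties and ordering**: canonical voxel order is ascending (x, y, z) with
  x the primary key; ICASSO components are ordered by decreasing $I_q$;
  hubs sort by membership count then component number.

## Design decisions that were genuinely open

* **Bootstrap dimension.** ICASSO resamples the *sample* dimension of
  spatial ICA — voxels — with replacement, then re-whitens. Resampling the
  pooled-time dimension would duplicate variables, not observations, and
  makes the whitening rank-deficient.
* **Exclusion order** in QC: stability, then artifact label, then extent.
  The report gives one reasoned row per exclusion, and retained + excluded
  always partition the input; re-running QC on its own output is a no-op.
* **Stepwise direction**: bidirectional ("stepwise" in the SPSS sense) at
  0.05/0.10, the defaults of the statistics packages used in clinical
  studies of this kind. Stepwise-by-p and best-subset-by-BIC are *not* the
  same selector: BIC's entry bar at n = 200 corresponds to roughly
  p ≈ 0.02, so a marginal candidate with p between ~0.02 and 0.05 is
  accepted by stepwise and rejected by BIC. The acceptance suite measures
  this agreement honestly rather than papering over it.
* **Sampling variability at clinical n.** With 40 patients, the realized
  $R^2$ of a planted model scatters substantially around its target
  (the calibration test asserts the cross-cohort sd is below 0.2); a
  single cohort's fitted $R^2$ can sit well away from the generating
  value with no estimator error at all. End-to-end recovery checks at
  this size are therefore rate-based across replicates, and the power of
  stepwise selection — not map or score recovery, which the tests show is
  essentially exact — is the binding constraint.
* **MDL sample count**: the number of voxels by default in the pipeline
  (the covariance is estimated over voxels); an effective-sample-size
  correction for spatial smoothness is a documented possibility but off —
  the generator plants spatially independent noise, and no smoothness
  estimate is available in general.

## Problem sizes

The test suite and acceptance script run at desk scale by design: grids of
14–20 × 14–20 × 8–10 voxels (≈ 500–1 500 in-mask voxels), 40–150 volumes,
cohorts of 4–55 subjects, 6–20 ICASSO runs, and 5–20 end-to-end
replicates. These sizes were chosen so each property remains sharply
testable (exact identities at 1e-8, recovery at 0.99+) while a full run of
every stage completes in minutes on one CPU.

## Known limitations

* Artifact and canonical-network labels are consumed, never inferred; no
  template matching is provided.
* Only dual regression is implemented for back-reconstruction (no
  PCA-transform GICA back-projection variants).
* No covariate adjustment in the domain models by default (a hook exists
  in the design but clinical confounding is out of scope), no
  multiple-testing correction across domains or components, and no
  cross-validation — the modeling stage reproduces the reporting
  conventions of the motivating study design, including their weaknesses.
* The LED schedule covers the seven listed drugs only; other conversion
  conventions can be supplied as a custom schedule.
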