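---
title: "Sub-organ ring decomposition and neural-network OAR dose prediction"
author: "ringdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-organ ring decomposition and neural-network OAR dose prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In high-dose-rate brachytherapy of locally advanced cervical cancer, a
stepping ^192^Ir source dwells inside an intrauterine tandem and, for bulky
or asymmetric tumors, inside metal needles inserted directly into the
target. Plan quality is judged by a handful of dose-volume-histogram (DVH)
numbers: D90 of the high-risk clinical target volume (HR-CTV) — the dose
covering 90% of the target — must be high enough, while D2cm³ of each organ
at risk (OAR: bladder, rectum, sigmoid colon) — the minimum dose to its
hottest 2 cm³ — must stay below tissue-specific EQD2 limits (here HR-CTV
D90 ≥ 85 Gy, bladder ≤ 90 Gy, rectum/sigmoid ≤ 75 Gy, all EQD2).

What an OAR can achieve, however, depends almost entirely on where that OAR
sits relative to the target: a rectum hugging the cervix will inevitably be
hotter than one 2 cm away. `ringdose` implements a knowledge-based
prediction of the *achievable* OAR dose from geometry alone, usable both as
a planning goal and as a quality-assurance (QA) gate: if a finished plan's
OAR dose ratio deviates from the prediction by more than a threshold, the
plan likely deserves another optimization pass.

## The method

**Features: sub-organ ring volumes.** The HR-CTV mask is externally
expanded into concentric distance shells ("rings") of width 0.3 cm,
realized as a Euclidean distance field on the voxel lattice: a voxel with
distance `d` to the HR-CTV joins ring `k` iff `(k-1)·w < d <= k·w`. The
intersection of ring `k` with an OAR is *sub-organ k*; its volume divided
by the whole OAR volume is the normalized sub-organ volume, the k-th
geometric feature. At most 15 rings are kept (4.5 cm stand-off); absent
rings contribute exact zeros so the feature vector has fixed length. The
HR-CTV volume (cm³) is appended as a 16th feature.

**Target: D2cm³/D90.** The per-fraction OAR hot-spot dose is normalized by
the target coverage dose of the same plan. The ratio is scale-free —
multiplying the dose grid by any constant cancels — so plans prescribed 6
and 7 Gy/fraction pool into one regression task.

**Model.** One independent network per OAR: inputs min-max scaled to
[-1, 1], one hidden layer of 10 tanh units, linear output, inverse target
scaling. Training is full-batch Levenberg–Marquardt on the scaled
residuals: each step solves `(JᵀJ + μI)δ = Jᵀe` with the analytic Jacobian
of the network; a step is accepted only if the training MSE strictly
decreases (then `μ ← μ/10`), otherwise `μ ← 10μ` and the step is retried —
interpolating between Gauss–Newton and gradient descent. Runs stop on
`μ > 10^10`, a gradient norm below `10⁻⁷`, 1000 accepted epochs, or six
consecutive accepted epochs without a validation improvement, returning the
best-validation weights. Because a single LM run can land in a poor local
minimum, the protocol launches many independent random initializations
(default 100; the scaled-down studies in the tests use 20) and keeps the run
with the lowest validation MSE.

**Split.** Plans are permuted uniformly and allocated 70/15/15 by
largest-remainder rounding (218 plans → 152/33/33). The default split is at
the plan level; `makeSplit(..., groupIds = patient_id)` keeps all fraction
plans of one patient in a single set for those who prefer to avoid
patient-level leakage, at the cost of slightly ragged set sizes.

**Evaluation and QA.** Regression R and MSE per split, the mean ± SD of
`Δ = |actual − predicted|` of the ratio, and a paired t test between
predicted and planned ratios over all sets (no significant difference is
the desired outcome — the prediction should be an unbiased surrogate of the
plan). The QA gate flags a plan when `|predicted − planned| > threshold`
(strict; default 0.10 of the ratio, configurable — no canonical value
exists, so institutions should calibrate it to their own tolerance).

## The synthetic phantom cohort

No public cohort of needle-insertion fraction plans exists, so the package
ships a generator whose defaults emulate the study conditions end to end,
at desk scale:

* **Lattice** 96³ voxels at 2 mm isotropic — CT-like resolution that keeps
  a full cohort generation within minutes on one CPU.
* **Anatomy.** HR-CTV: central ellipsoid, semi-axes U(15, 30) mm (volumes
  roughly 15–110 cm³). Bladder: anterior ellipsoid; rectum: posterior
  vertical tube; sigmoid: superior curved tube — each placed at an
  independently sampled surface gap U(0, 20) mm from the HR-CTV (organs may
  abut, never overlap). The shapes are coarse geometric primitives, not an
  anatomical atlas; ranges were chosen once as clinically plausible organ
  volumes and stand-offs.
* **Dwells.** A tandem line through the HR-CTV centroid plus 2–8 needles
  (probabilities 0.25/0.30/0.20/0.10/0.07/0.05/0.03 on 2…8, mean 3.71)
  arranged template-like at equal azimuthal spacing on ~60% of the
  cross-section, dwell step 2.5 mm (the usual afterloader step). Needle
  dwells carry base weight 0.3 vs 1.0 for the tandem (tandem-dominant
  loading); all weights get multiplicative log-normal noise (σ = 0.1) as
  plan-to-plan variability beyond geometry.
* **Dose.** A bare inverse-square point kernel, `w·k/max(r, 1 mm)²`,
  superposed over dwells; no anisotropy or radial dose function (TG-43
  tables are deliberately out of scope — geometry, not absolute dosimetry,
  drives the learning task). Every plan is rescaled so HR-CTV D90 equals
  its 6 or 7 Gy prescription, the phantom counterpart of the clinical
  practice of normalizing plans to coverage; the D2cm³/D90 target is
  scale-free either way.
* **Cohort.** Consecutive groups of 2–5 plans share a patient id
  (multi-fraction patients); everything is a deterministic function of
  `(seed, plan index)`.

What the phantom does *not* emulate: realistic organ shapes and deformation
between fractions, applicator/ovoid geometry, source anisotropy,
heterogeneity corrections, and human planner trade-offs. Passing tests on
this cohort therefore demonstrate that the pipeline recovers geometry-driven
dose relationships under controlled conditions — not clinical accuracy on
real patients, which requires institutional data.

```{r example}
library(ringdose)
cohort <- generateCohort(phantomParams(seed = 42), 220)
split <- makeSplit(nrow(cohort), seed = 42)
fx <- cohortFeatures(cohort, "rectum")
fit <- trainWithRestarts(fx$features, fx$target, split,
                         trainingConfig(nRestarts = 20, seed = 42))
evaluateModel(fit$model, cohort, "rectum", split)$report
```

## Numerical choices and conventions

* **Ring membership** uses the half-open interval `((k-1)w, kw]`; a
  convention had to be fixed and is pinned by tests. OAR voxels *inside*
  the HR-CTV (distance 0) are reported separately (`insideVolumeCc`) and
  are not features: the rings measure stand-off geometry only.
* **Distances** are voxel-center-to-region Euclidean distances computed by
  an exact separable distance transform with anisotropic spacing handled
  inside the transform (never by resampling). Tests verify bit-level
  agreement with exhaustive pairwise search. This discrete semantics
  carries a quantization artifact worth knowing about: against an *ideal*
  sphere of radius R voxelized at spacing h, the transform overestimates
  the continuous distance by ~0.2–0.3·h on average (the nearest interior
  voxel center sits slightly inside the surface). Ring volumes of
  thin shells therefore deviate from closed-form sphere-shell volumes by
  roughly `δ·4πr²`, a few percent at h = 1 mm — visible in the analytic
  concentric-sphere checks and inherent to mask-based pipelines.
* **DVH metrics** sort voxel doses and interpolate the cumulative-volume
  DVH linearly between voxel dose levels, which removes quantization jumps;
  volume accounting is voxel-count × voxel volume. `doseAtVolume` is
  non-increasing in the volume argument and exactly scale-covariant.
* **EQD2** uses α/β = 10 Gy for the target and 3 Gy for OARs by default —
  standard clinical convention, configurable, and explicitly an assumption.
* **Scaling** maps each training variable's (min, max) to (−1, 1) without
  clipping; a constant variable maps to 0 with a warning (distant rings are
  often identically zero in a cohort — harmless, the network ignores them).
* **Initialization** is uniform(−0.5, 0.5) scaled by 1/√fan-in under a
  seeded stream; the restart protocol makes the exact law uncritical.
* **Targets** are per-fraction physical dose ratios, not EQD2 ratios; the
  ratio makes the distinction largely immaterial, and the choice is
  recorded here as an assumption.
* **Degenerate inputs** fail loudly: empty masks, volume requests beyond
  the mask, constant vectors in correlation/t tests, untrained models,
  dwells outside the lattice, lattices too small for sampled organs (the
  error names the organ).

## Design decisions where the method description was open

* *"Train 100 iterations … chose the best result"* admits two readings —
  100 epochs of one run, or 100 independent runs. Implemented as 100
  random-initialization restarts with best-validation selection, because
  single-run LM epochs are already governed by early stopping; the epoch
  cap is separately configurable for the other reading.
* *One network per OAR* (three models) rather than one three-output
  network, matching the per-OAR reporting of accuracy; a shared network is
  a straightforward variant but is not the default.
* *Hidden size 10*: the customary default of neural net-fitting tools;
  config-exposed.
* *Feature set*: normalized ring volumes + HR-CTV volume. The own-OAR
  volume participates in the correlation report but not in the model
  features by default (`cohortFeatures(..., includeOarVolume = TRUE)` adds
  it as a 17th feature).
* *Ring count*: the cap is 15; whether 5 or 15 rings were used in the
  original correlation tables is not decidable, so `nRings` is exposed
  (fixed-length zero-padded features keep the network interface stable).
* *Expansion dimensionality*: rings are fully 3D; a slice-wise 2D variant
  would change sub-organ volumes near the target's superior/inferior poles
  and is intentionally not implemented.

## Problem sizes used by the shipped studies

The packaged tests and the acceptance script run the full protocol on a
218–220-plan cohort at 96³ × 2 mm with 20 restarts per OAR — a deliberate
desk-scale choice (minutes on one CPU) that preserves the cohort size and
split arithmetic of the study design while scaling the restart count down
from 100. Oracle checks (brute-force distances, closed-form shells and DVH,
least-squares and planted-network recovery) run on grids up to 165³ and
cohorts up to a few hundred rows.

## Known limitations

* The phantom's organ shapes are primitives; its dose engine is a bare
  point kernel. Conclusions about clinical accuracy require real plans.
* The QA threshold default (0.10) is a placeholder convention; it should be
  set from an institution's observed Δ distribution.
* Δ is summarized with the sample (n−1) standard deviation.
* The paired t test is run over all sets pooled (per-set tests are
  available via `fitReport` on subsets).
* NIfTI is the only mask/dose interchange format; a DICOM-RT adapter is an
  extension point, not core.
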