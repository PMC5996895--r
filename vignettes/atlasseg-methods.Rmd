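---
title: "Segmenting acute stroke diffusion lesions with Youden-index trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting acute stroke diffusion lesions with Youden-index trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasseg)
```

## The problem

In acute ischemic stroke, tissue that is bright on diffusion-weighted MRI
(DWI, b = 1000 s/mm²) with a reduced apparent diffusion coefficient (ADC) is
taken to be irreversibly damaged — the ischemic core. Its volume drives
treatment decisions, so a fast, operator-independent delineation that agrees
with expert outlines is valuable. Fixed intensity thresholds travel poorly
across scanners and cohorts; `atlasseg` instead learns a voxel classifier
from expert-labelled cases and regularizes it spatially.

## Feature construction

Each voxel is described by four values.

**Normalized DWI.** Raw DWI intensities are arbitrary units. Every axial
slice is divided by the mean DWI over the brain-mask voxels of the
contralateral (healthy) hemisphere of that slice, making 1.0 "normal
tissue". The contralateral side is given explicitly or chosen automatically
as the hemisphere with the smaller count of voxels above the 98th percentile
of a roughly normalized volume; ambiguous choices (counts within 10%) are
flagged. Mask-edge slices whose voxels are pure noise fall back first to the
whole-slice mean, then to the volume-wide brain mean; an all-zero slice
passes through as zeros. Only a volume whose brain-wide mean is non-positive
is an error.

**ADC.** Used in native units: ADC is already an absolute physical quantity
(mm²/s) and insensitive to T2 shine-through, which is precisely why it
complements DWI. We deliberately do not standardize it.

**Mirror-corrected DWI and ADC.** Healthy brains are roughly left–right
symmetric, and many confounds (susceptibility artifacts, normal bright
structures) are bilateral. The mirror transform is a flip of the left–right
axis about the grid center composed with a 6-DOF rigid correction estimated
by minimizing the mean squared b0 intensity difference to the flipped b0
(Nelder–Mead over translations and rotations, trilinear sampling on a
deterministic subsample of the slightly dilated brain mask — the
brain/background edge is what constrains the fit, as interior tissue is
nearly flat). A mirrored image is smoothed with an isotropic Gaussian
(default σ = 2 mm) and passed through a critical-intensity filter that
replaces each voxel by the most critical value in its 3×3×3 neighbourhood —
the maximum for DWI, the minimum for ADC — providing tolerance to residual
registration error. The mirror-corrected map is the original minus this
processed reflection: bilateral structure cancels, unilateral lesions
survive with their critical sign. If the optimized fit explains no more of
the masked variance than chance (as on a structureless noise volume), the
transform falls back to the pure midplane flip with a warning.

The mirror-corrected DWI is computed from the *normalized* DWI (the two
hemispheres are then on one scale); the mirror-corrected ADC from native
ADC. On a noiseless, exactly symmetric phantom with σ = 0 the corrected DWI
is ≤ 0 and the corrected ADC ≥ 0 everywhere — an exact order-statistic bound
that the test suite asserts literally, and that positive corrected-DWI
support is confined to the lesion dilated by the filter radius.

## The tree

Growth is exhaustive and deterministic. At a node, for each variable, every
midpoint between consecutive distinct sorted values is scanned as a
threshold and scored by Youden's index *J* = sensitivity + specificity − 1,
with "predicted positive" meaning value ≥ threshold. Because lesions are
bright in some variables and dark in others, the scan is orientation-free:
it maximizes |J|. Equal scores resolve to the smallest threshold, then the
lowest variable index — determinism is a design requirement, since
retraining must reproduce a model exactly. The winning variable splits the
node into a ≥-branch and a <-branch; growth stops at single-class nodes, at
an optional depth cap, or when no variable varies within the node (mixed
labels on identical feature vectors become a "forced" leaf).

Every node stores *p*(*N*) = (*n*₁ + 1)/(*n* + 2), where *n*₁ of the *n*
voxels at the node are in-lesion. Compared with the raw fraction *n*₁/*n*
this pseudo-count estimate shrinks toward 0.5 as nodes get small, so deep,
thinly populated leaves cannot claim certainty. An empty node would score
exactly 0.5.

Depth is selected by an inner leave-one-patient-out loop: for each training
patient a tree is grown on the others, the held-out voxels are scored with
the depth-*d* predictions *p_d*(*x*) for every *d* from 0 to the tree's
height, and the AUC-optimal depth recorded (ties toward the smaller depth —
smaller trees on equal evidence). The final tree is pruned to the median of
these optima; with an even patient count we take the lower middle value,
again preferring the smaller model. Pruned-tree predictions are identical to
depth-limited traversal of the unpruned tree, a property the suite checks
exhaustively.

Inside the cross-validation pipeline trees are grown with a depth cap of 12:
predictions at any depth below the cap equal those of full-purity growth
followed by pruning, and selected depths in practice stay well below it
(typically 2–7 under the default synthetic conditions). `build_tree()`
itself defaults to unlimited growth.

## Spatial regularization

The voxelwise probability map is smoothed with an isotropic 3-D Gaussian
(default σ = 2 mm, matching the preprocessing scale), thresholded at 0.25,
then morphologically closed (recovering false-negative speckle inside the
lesion) and opened (removing false-positive islands). The threshold sits
below ½ because non-lesion voxels vastly outnumber lesion voxels, biasing
tree probabilities low. Two numerical choices matter:

* Smoothing at the brain boundary is mask-renormalized — `smooth(p·m)/
  smooth(m)` inside the mask — so cortical lesion probability is not diluted
  by out-of-brain zeros; a constant map is preserved exactly.
* The structuring element is the 3×3×3 cube (the radius-1 Chebyshev ball).
  With the 6-neighbour cross element, opening clips the corners of any solid
  region; the cube makes close-then-open exactly idempotent on solid
  axis-aligned regions, giving clean degenerate-case behaviour (a constant
  in-brain probability of 0.3 returns the brain mask itself).

Threshold comparison is inclusive (≥) for determinism at the boundary.

## Evaluation protocol

Outer leave-one-out cross-validation: for each held-out patient the entire
training procedure — including the inner depth selection — runs on the
remaining patients only, so no voxel of the held-out patient can influence
its own model (the suite checks this by poisoning a held-out patient's
labels and asserting its model is bit-identical). Masks are scored by Dice;
volume agreement by the sample SD of predicted-minus-expert volumes; method
contrasts by paired Wilcoxon signed-rank tests (`stats::wilcox.test`, exact
for small untied samples).

The comparison baselines are per-patient *optimal* two-threshold bands on
normalized DWI and on ADC: over all intensity intervals [lo, hi] with
endpoints among the observed in-brain values (± unbounded sentinels), the
band maximizing Dice against that patient's own expert mask. These are
upper bounds unattainable prospectively, which is what makes them a hard
benchmark. The scan is exact (quadratic in distinct values) up to 1024
distinct values, beyond which values are first binned to 256 observed
quantiles; tie-breaks prefer the widest band, then the smallest lower
threshold. On the normalized-DWI baseline a config switch allows raw DWI
instead; normalized is the default since the bands must be comparable
across patients.

Dice conventions for degenerate masks: two empty masks score 1, exactly one
empty scores 0 — continuity and determinism at the boundary.

## The synthetic cohort

Clinical DWI cohorts cannot be redistributed, so every stage is exercised on
a seeded generator whose defaults are the package's study conditions: 12
patients on a 32×36×30 grid of 2.5 mm voxels; an ellipsoidal two-hemisphere
"brain" (b0 ≈ 1000 inside, 0 outside); DWI background 100 (arbitrary
units), ADC background 800×10⁻⁶ mm²/s; one ellipsoidal lesion per patient in
a random hemisphere, 2–10 ml, DWI ×1.5–2.5 and ADC ×0.4–0.7; additive
Gaussian noise with sd 5% of each tissue mean; a small random head offset
(sd 0.5 mm) that the mirror registration must recover; smooth symmetric
low-frequency tissue modulation plus per-slice intensity drift of ±10% on
the relative-scale channels (DWI, b0) — the drift is exactly what slice-wise
normalization must remove — while ADC, a quantitative map, carries none.

Three mirrored bilateral artifact pairs per volume are lesion-like in both
channels (DWI-bright, ADC-dark; the first pair reuses the lesion's own
contrast draws, so no intensity band can separate it from the lesion), and
strictly symmetric about the head midplane: a mirror-symmetric exclusion
zone (the lesion plus a one-voxel rim and its mirror image) is carved out of
every pair, because a half-carved pair would itself be a unilateral anomaly
and legitimately segmented. These artifacts are the property mirror
correction exists for: they saturate any per-patient ADC band's Dice while
leaving the tree's mirror-corrected features clean.

What the generator does *not* emulate — and hence what passing tests cannot
show about clinical data: realistic anatomy (no atlas or template), partial
volume effects at lesion borders, scanner-specific noise spectra, multi-site
intensity variation beyond the drift model, non-ellipsoidal lesion shapes,
and expert-rater variability (labels are exact geometric ground truth).
Dice values near 0.9 here are accordingly optimistic relative to the ~0.6
range typical of expert-agreement studies on clinical cohorts.

At the default sizes (≈ 9,000 brain voxels per patient, ≈ 100,000 training
voxels per fold) the full outer LOOCV with nested depth selection runs in
about a minute on one core; these sizes were chosen so the complete
protocol, including its bit-reproducibility re-run, stays comfortable for
routine testing while leaving every algorithmic path at realistic relative
scales (lesions 2–10% of brain volume).

## Other design choices on open points

* Candidate split thresholds are midpoints between consecutive distinct
  values — the standard exhaustive choice when the optimum is scanned
  anyway.
* Whether training should exclude non-brain voxels is settled as yes: the
  feature table contains brain-mask voxels only, matching the domain the
  model is applied to.
* All channels must arrive pre-resampled on one grid; expert masks are
  binarized at 0.5 on load.
* Trees serialize to JSON with thresholds duplicated as C99 hex floats and
  leaf probabilities re-derived from the stored counts, so a reloaded model
  routes every voxel identically to the in-memory one.
* Optional deterministic thinning of non-lesion rows
  (`subsample_negatives`) bounds table sizes on large cohorts; it is off by
  default and unused in the shipped conditions.

## Limitations

The method inherits the expert outlines it is trained on, including their
systematic biases; it assumes approximate bilateral symmetry (bilateral or
midline-crossing infarcts weaken the mirror features); the rigid mirror
registration has no deformable component; and the depth-selection median is
a blunt regularizer — patients with atypical lesion texture can prefer very
different depths. On synthetic data the optimal-DWI band occasionally
matches the full pipeline, which simply reflects how favourable an oracle
band is when one channel alone nearly separates the classes.
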