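---
title: "Self-adaptive clustering segmentation of PET lesions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-adaptive clustering segmentation of PET lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petsac)
```

## The segmentation model

`petsac` segments FDG-avid lesions *inside observer-drawn ROIs*.  The
premise is that a loose 3D region around a lesion contains essentially
two tissue populations — background and lesion — plus a partial-volume
"border" band created by the scanner's point-spread function.  All
methods operate on the one-dimensional distribution of SUVs within one
ROI; no spatial regularization is used, so a voxel's class depends only
on its intensity.  This keeps every method deterministic and cheap, at
the price of ignoring texture (see Limitations).

Two families are implemented:

* **Thresholding.**  `segment_threshold_abs()` keeps voxels with
  SUV ≥ 2.5; `segment_threshold_rel()` keeps voxels above 41% of the
  ROI's own SUVmax.  Comparisons are boundary-inclusive (≥), so at
  fraction 1.0 the SUVmax voxel itself survives.
* **Clustering.**  `kmeans_1d()` runs Lloyd's algorithm on the ROI's
  SUVs; `fit_gmm_map()` fits a univariate Gaussian mixture by EM and
  assigns each voxel to the class with the highest posterior
  probability.  With `k = 2` the lesion is the higher-mean class.

### The self-adaptive configuration (SAC) rule

A fixed two-class split tends to include too much or too little of the
partial-volume border, depending on contrast.  The SAC variant fits
*three* classes (background `m1`, border `m2`, lesion `m3`, means
ascending) and computes the contrast coefficient

$$\mathrm{coef} = \frac{m_3 - m_1}{m_3 + m_1} \in [0, 1],$$

an asymmetry index of the extreme class means.  The merge rule is:

| condition | action | lesion |
|---|---|---|
| `coef < 0.90` | merge the two lower classes | class 3 alone |
| `coef ≥ 0.94` | merge the two higher classes | classes 2 ∪ 3 |
| otherwise | refit with 2 classes | class 2 of 2 |

The intuition: at very high contrast the border band is still far above
background, so it belongs with the lesion; at moderate contrast the
border is closer to background and keeping it would inflate the volume;
in the narrow intermediate regime a plain two-class split is the safer
partition.  The cut-offs 0.90/0.94 are the rule's published operating
points and are exposed as configurable parameters
(`segment_sac(..., thresholds = )`).

Which classes constitute the "lesion" after each merge is not uniquely
determined by the rule's statement; `petsac` resolves it so that the
lesion is always the surviving highest-mean cluster set, which matches
the border-handling intuition above.  Note that `coef ≥ 0.94` requires
`m3 ≥ 32 m1`: with a typical soft-tissue background near SUV 1 the
merge-two-higher branch fires only for very hot lesions on very cold
backgrounds (lung, fat); on the default phantoms the dominant branch is
merge-two-lower.

## Numerical choices

* **Percentile initialization.**  Centroid *i* of *k* starts at the
  `100·(2i−1)/(2k)` percentile (linear interpolation, R type 7) of the
  ROI's SUVs — symmetric, spread over the distribution, and
  deterministic, so repeated runs are bit-identical.  No randomness
  enters any segmentation method.
* **Lloyd iteration** stops when no assignment changes, or at 300
  sweeps.  If the converged model has an empty class or two classes
  with equal means, duplicates are merged and the fit is re-run with
  `k − 1`; if `k` would fall below 2 the ROI is reported as degenerate.
* **EM** is initialized from the k-means classes (means, proportions,
  within-class variances), stops when the log-likelihood gain drops
  below `1e-6` per sample, caps at 500 iterations (returning the last
  iterate with a warning), and floors variances at `1e-8` times the
  overall variance so point-mass classes cannot collapse the
  likelihood.  Posteriors are evaluated in log space.
* **Degenerate ROIs** (fewer distinct values than classes — e.g. a
  noise-free two-valued phantom ROI under the 3-class SAC fit) fall
  back to the 41% relative threshold for that ROI with a warning, and
  the fallback is recorded in `roi_info$branch`.  This keeps batch runs
  alive and auditable rather than failing a whole patient.
* **Connectivity.**  Disconnected lesions are defined by
  26-connectivity by default (faces, edges, corners) — the most
  permissive standard convention — configurable to 6 or 18.  This
  choice decides whether a conglomerate counts as one lesion or
  several, which matters for representative-lesion analyses.
* **Dice of two empty masks** is defined as 1 (agreement on absence,
  with a warning); one empty mask gives 0.
* **ICC.**  Feature agreement uses the two-way random-effects,
  single-measure, absolute-agreement form ICC(2,1), computed from the
  `stats::aov()` mean squares.  Absolute agreement is the right form
  here because a segmentation method that systematically inflates MTV
  should score worse even if it ranks patients identically.

## Feature definitions

The default registry has 31 features: 14 first-order intensity features
(including SUVpeak, the best mean over a 3×3×3-voxel neighborhood,
border-truncated rather than zero-padded to avoid biasing edge peaks
downward), MTV (voxel count × voxel volume, cm³), TLG (MTV × SUVmean),
7 geometric features and 8 dissemination features.  Entropy and
uniformity use 64 fixed-width bins over `[0, SUVmax]` of the region.
Skewness and kurtosis use population moments (kurtosis not
excess-corrected).

**Surface areas are digital.**  Surface area is the summed area of
exposed voxel faces.  This makes the cube identities exact (a voxel
cube scores sphericity `(π/6)^(1/3) ≈ 0.806`) but overestimates the
geometric area of smooth shapes by a factor approaching 3/2, so a
digitized ball scores sphericity near 2/3, not 1.  Sphericity and its
derivatives are therefore *relative* shape indices, comparable across
lesions segmented on the same grid, not absolute geometric quantities.

**Dissemination.**  Published dissemination panels vary and the exact
composition used alongside this segmentation family is not fully
enumerable from public sources; the 8 features here (lesion count,
maximum and mean/SD pairwise centroid distances, maximum distance from
the highest-TLG lesion, maximum surface-to-surface spread, MTV
dispersion, and the mean distance from the MTV-weighted burden
centroid) are a documented, literature-consistent stand-in.  Distances
are between voxel centers in physical mm; centroids are unweighted
except the burden centroid (MTV-weighted).

## What the phantoms emulate — and what they do not

`phantom_cohort()` encodes the study conditions: 4 mm isotropic voxels
(the reconstruction grid of the time-of-flight scanner class this
workflow targets), a 7 mm-FWHM Gaussian point-spread function, a
uniform background at SUV 1.0, additive Gaussian noise with SD 0.1
(10% of background, applied after blurring, clipped at 0), lesion SUVs
sampled from 4.5–10.3 and volumes from 1.3–9.7 cm³ — the interquartile
spans reported for staging lymphoma populations — with 1–4 mildly
anisotropic ellipsoidal lesions per patient.  ROIs are the ground-truth
lesions dilated by 3 voxels; two "observers" are simulated by
dilating/eroding each ROI by a seeded random amount up to ±1 voxel with
a jittered structuring element.

Deliberate simplifications: post-reconstruction PET noise is
approximated as Gaussian (not Poisson projection noise), the background
is textureless, lesions are homogeneous ellipsoids, and no anatomy
(liver, bladder, brain) abuts the lesions.  Consequently, passing tests
demonstrate correctness of the algorithms and their behavior under
partial-volume and noise degradation — they do not demonstrate clinical
accuracy on heterogeneous lesions near high-uptake organs, where the
intensity-only assumption is most stressed.

Two phantom-specific behaviors are worth knowing:

* On *noise-free, blur-free* phantoms every ROI holds exactly two
  intensity values, so the 3-class SAC fit is degenerate by
  construction and the documented fallback path (41% threshold) is what
  recovers the ground truth there.
* The 41% rule's reproducibility under ROI perturbation depends
  strongly on contrast.  At 4.5–10:1 its cut-off lies far above every
  background voxel, so perturbing the loose ROI boundary changes
  nothing and its inter-observer Dice saturates at 1 — a comparison
  with no discriminative content.  The reproducibility advantage of the
  SAC methods is therefore evaluated on a low-contrast companion cohort
  (lesion SUV 2.0–3.5), where the threshold falls into the intensity
  band that ROI perturbation reshuffles.  With 20-patient cohorts the
  median of such Dice distributions carries visible sampling noise, so
  near-ties between methods can invert between seeds; the acceptance
  script reports both cohorts' medians.

## Problem sizes

The test suite and the acceptance script run on 48³-voxel patients
(24³–32³ for unit fixtures), cohorts of 20 patients, 100 clustering
oracle instances up to n = 500, 1000 random mask pairs for the Dice
oracle and 100 matrices for the ICC oracle.  These sizes were chosen so
the whole suite completes in a few minutes on a single core while
keeping each statistical check comfortably powered for its tolerance.

## Known limitations

* Intensity-only clustering cannot separate a lesion from an adjacent
  equally-hot structure inside the same ROI; the ROI convention (avoid
  enclosing normal high-uptake tissue) is part of the method.
* The EM fit on blurred lesions has two rival solutions (border band
  absorbed into the lesion class or into the middle class); which one
  EM reaches depends on the data, and for large low-contrast lesions
  this is the dominant source of volume error — a property of 3-class
  intensity mixtures under a wide PSF, not of the implementation.
* SUV calibration supports body-weight SUV only, and images are assumed
  decay-corrected to scan start by the scanner.
* No resampling: volumes and ROI maps must share one voxel grid
  (checked to 10⁻³ mm).
* DICOM, RT-STRUCT, CT-guided segmentation and deep-learning inference
  are out of scope.
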