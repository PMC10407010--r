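# petsac

Semiautomatic segmentation and quantification of FDG-avid lesions on PET
volumes, for imaging scientists who need reproducible lesion delineation
without slice-by-slice manual contouring.

The workflow mirrors clinical practice in lymphoma and other
multi-lesion diseases: an observer draws a loose 3D region of interest
(ROI) around each lesion, and the algorithm delineates the lesion inside
each ROI from the voxel intensities alone.  `petsac` implements the
classical semiautomatic family —

* **absolute SUV threshold** (default SUV ≥ 2.5),
* **relative threshold** (default 41% of the per-ROI SUVmax),
* **2-class k-means** on the ROI's SUV distribution, with percentile
  initialization of the centroids,
* **2-class Bayesian classification**: a univariate Gaussian mixture fit by
  EM, each voxel assigned by maximum a posteriori probability,

and the **self-adaptive configuration (SAC)** variant of the two clustering
methods.  SAC first fits *three* classes (background, lesion border,
lesion), computes the contrast coefficient

```
coef = (m3 − m1) / (m3 + m1)          m1, m3 = lowest/highest class mean SUV
```

and applies an empirical merge rule: if `coef < 0.90` the border class
joins the background (the lesion is the highest class alone); if
`coef ≥ 0.94` the border joins the lesion; otherwise the ROI is re-fit
with just two classes.  The resulting mask is split into disconnected
lesions by 26-connectivity component labeling.

Downstream, the package quantifies each lesion and the patient's total
tumor burden: first-order SUV statistics (SUVmax, SUVmean, SUVpeak over
3×3×3-voxel neighborhoods, entropy, …), metabolic tumor volume
(MTV, cm³), total lesion glycolysis (TLG = MTV × SUVmean), geometric shape
features, and 8 dissemination features describing how far apart the
lesions lie.  Agreement between segmentation sources is measured by the
Dice coefficient (patient basis: union of all ROI masks) and by the
absolute-agreement intraclass correlation ICC(2,1) on the extracted
features.

Because clinical images cannot ship with a package, `petsac` includes a
digital phantom generator: ellipsoidal lesions of configurable
lesion-to-background contrast on a uniform background, Gaussian
point-spread blurring, additive noise, automatically derived enclosing
ROIs, and seeded "observer" perturbations of those ROIs.  Every result
below is computed on such phantoms with known ground truth.

## Worked example

```r
library(petsac)

# one synthetic patient: two FDG-avid lesions, 7 mm PSF, 10% noise
cohort <- phantom_cohort(1, seed = 7, n_lesions_range = c(2, 2))
pat <- cohort[[1]]
pat$volume
#> <pet_volume> 48x48x48 voxels, spacing 4x4x4 mm, SUV range [0.569, 7.75]

# self-adaptive Bayesian segmentation inside the observer's ROIs
seg <- segment(pat$volume, pat$obs1, method = "sac-bayes")
seg$roi_info
#>   label n_roi n_selected      coef          branch
#> 1     1   788         98 0.6767646 merge_two_lower
#> 2     2   711         74 0.5781659 merge_two_lower

# agreement with the ground truth and lesion quantification
dice(seg$mask, pat$truth$labels > 0)
#> [1] 0.966967

lesions <- label_lesions(seg)
feats <- patient_features(pat$volume, lesions, patient_id = pat$id,
                          method_id = "sac-bayes", observer_id = "obs1")
feats[, c("scope", "suv_max", "suv_peak", "suv_mean", "mtv_cm3", "tlg_cm3")]
#>          scope  suv_max suv_peak suv_mean mtv_cm3  tlg_cm3
#> 1     lesion_1 7.747318 7.048431 5.464842   6.272 34.27549
#> 2     lesion_2 5.556715 4.713816 3.985886   4.736 18.87715
#> 3 total_burden 7.747318 7.048431 4.828547  11.008 53.15264
```

Both ROIs have moderate contrast (`coef` ≈ 0.58–0.68 < 0.90), so the SAC
rule merges the border class into the background and keeps the
highest-intensity class as the lesion; the resulting masks overlap the
ground truth with Dice 0.97.  The feature table reports each disconnected
lesion and the pooled total burden; MTV is physical volume in cm³ and TLG
its SUVmean-weighted counterpart, so lesion 1 (6.27 cm³, SUVmean 5.46)
carries TLG 34.3 cm³.

A command-line wrapper over the same functions is installed as
`exec/petsac` (subcommands `phantom`, `segment`, `features`, `evaluate`),
writing NIfTI masks with JSON sidecars that record every parameter and
per-ROI branch decision.

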