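---
title: "Radiomic tractometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic tractometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `radtract`, the
conventions the implementation commits to, and the reasoning behind the
choices that were genuinely open. It states no empirical numbers beyond
what the package's tests and `scripts/acceptance.R` compute themselves.

## The pipeline

A tract is a bundle of streamlines — ordered 3-D polylines in RAS world
millimetres — analyzed against a voxel grid with a 4×4 affine. The
pipeline is:

1. **Reorientation.** Streamlines are flipped to a common start→end
   direction, either toward a start-region mask or, absent one, by the
   orientation that minimizes summed point distance to the longest
   streamline (both resampled to 20 points). Exact ties never flip.
2. **Centerline.** The pointwise mean of all streamlines after arc-length
   resampling to `n` points. For `n = 1` the "centerline" is the mean of
   the streamlines' arc-length midpoints.
3. **Envelope.** Every voxel traversed by any streamline, followed by one
   pass of morphological closing with the full 3×3×3 (26-connected)
   structuring element to fill pinholes in sparsely seeded bundles.
   Traversal samples each streamline at quarter-voxel arc steps and maps
   to the nearest voxel center; the sampling error is far below the voxel
   size and the convention is fixed so that independent oracles can
   reproduce it exactly.
4. **Parcellation.** Three schemes. *Static*: resample each streamline to
   `n` points; point `i` belongs to parcel `i`. *Centerline*: label every
   (densely resampled) streamline point with the nearest centerline
   point. *Voxel* (the radiomic scheme): label every envelope voxel with
   the nearest centerline point, producing an integer label map.
   Nearest-point ties always break to the lower index; this makes the
   labeling deterministic and testable against brute force.
5. **Features.** Classic profiles (per-parcel means of a map sampled at
   streamline points, trilinear interpolation) or the 105-feature
   radiomics set per parcel × map.
6. **Evaluation.** Constant-feature removal → correlation pruning →
   univariate k-best, refit inside every cross-validation fold; random
   forest (100 trees, maximum depth 4, Gini impurity, √p features per
   split, bootstrap resampling — the library defaults, deliberately
   untuned); ten leave-one-out cross-validations with seeds 0..9; pooled
   out-of-fold class probabilities per repetition scored by one-vs-rest
   AUROC; paired DeLong comparison between pipelines with the mean-p <
   0.05 rule per class (any class significant ⇒ comparison significant).

### Parcel count

`n` adapts to tract length: `n = n_voxels / v`, where `n_voxels` is the
per-subject mean over streamlines of the number of *distinct* voxels each
streamline traverses and `v` is the desired parcel thickness in voxel
units along the tract. The returned count is the rounded (half-up) mean
over up to ten randomly drawn subjects and is then fixed for the whole
cohort. Whether "voxels traversed" means distinct voxels per streamline
or total visits is ambiguous in the tractometry literature; distinct
voxels per streamline is chosen because it is invariant to the streamline
step size. `v = 5` is the working default throughout the examples.

## The 105-feature set

Per parcel and map: 18 first-order, 14 shape, and 73 texture features
(GLCM 22, GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14), named
`{map}__parcel{i:03d}__{class}__{feature}`. The member lists follow the
widely used IBSI-aligned reference sets with exactly these cardinalities;
the GLCM family omits the two historically deprecated duplicates (sum
average ≡ joint average for symmetric matrices, dissimilarity ≡
difference average) and the maximal-correlation coefficient, which is how
the 22-feature count arises. Cardinalities are enforced by test. The goal
is a standardized, well-defined feature dictionary — not bit-exact
replication of any specific third-party implementation.

**Discretization.** Texture matrices are computed on integer gray levels.
The default is a fixed bin *number*, G = 32, spanning the in-mask
min–max of each parcel ROI: FA lives in [0,1] while diffusivities are of
order 10⁻³ mm²/s, so a relative rule behaves identically across maps. A
fixed bin *width* is available (`radiomics_config(bin_width =)`, also via
the YAML config) for protocols that need absolute comparability across
subjects; which of the two a given study should use is a genuine
protocol decision, so it is exposed rather than hard-coded. A constant
ROI collapses to a single level (G = 1).

**Direction handling.** GLCM and GLRLM are computed per direction over
the 13 unique 3-D distance-1 directions and the features are averaged
over directions; GLSZM, NGTDM and GLDM are single-matrix constructions on
the 26-neighborhood. GLDM uses similarity tolerance α = 0 and indexes
dependence sizes as (number of equal neighbors + 1) so that isolated
voxels occupy column 1 and the inverse-square size weights stay finite.

**Degenerate conventions,** chosen once and tested: constant ROI ⇒
first-order entropy 0, uniformity 1, skewness/kurtosis 0; single-level
GLCM ⇒ correlation 1, joint energy 1; flat NGTDM ⇒ coarseness capped at
10⁶; texture families with no valid voxel pairs ⇒ features 0 with a
warning; empty parcels ⇒ missing values (never silent zeros), imputed
from training medians during selection.

### Shape features and the isosurface

Mesh volume and surface area come from an isosurface of the parcel mask:
marching tetrahedra (6-tet cell decomposition) on the *signed Euclidean
distance field* of the mask (exact squared-distance transform via the
separable lower-envelope algorithm), lightly smoothed with a Gaussian of
σ = 0.6 voxels. The zero level of the signed distance field sits halfway
between adjacent inside/outside voxel centers; smoothing removes the
residual voxel staircase that otherwise inflates surface area
substantially. σ = 0.6 was calibrated once against the analytic sphere
(area and volume simultaneously close to their closed forms); masks so
small that smoothing erases them fall back to the raw distance field, so
single-voxel parcels still yield a positive mesh. Volumes are computed
exactly for the piecewise-linear surface (per-tetrahedron clipping), not
by voxel counting — voxel volume is reported separately.

Axis lengths are 4·√eigenvalue of the population covariance of voxel
center coordinates in physical units; degenerate (planar/linear) masks
get zero least-axis and flatness 0 rather than an error. Maximum
diameters are largest pairwise distances between corners of surface
voxels (so a 10³-voxel cube of 1 mm spacing has 3-D diameter √300); the
2-D variants restrict to fixed-index planes. Shape features depend only
on the mask and are therefore identical across the four maps of a
parcel; they are computed once and shared.

## Feature selection

The cascade is: (1) drop zero-variance features; (2) scan columns in
order and drop any feature whose |Pearson r| with an already-kept earlier
feature exceeds 0.95 — keeping the *earlier* member is the deterministic
convention, since which member to drop is underdetermined; (3) keep the
top-k features by univariate F (one-way ANOVA F against the class label,
or the F implied by the linear correlation for regression), ties broken
by column order. The strict inequality at the 0.95 boundary carries a
10⁻¹² guard so that analytically-exact boundary correlations are not
dropped by floating-point noise. The whole cascade is fit on training
rows only and applied to held-out rows by feature name; a leakage test
poisons held-out rows and asserts the kept set is unchanged.

## Evaluation statistics

AUROC is the tie-aware normalized Mann–Whitney statistic (midranks, ties
contribute 1/2) — asserted equal to `wilcox.test`'s U on random inputs.
The DeLong comparison is the fast midrank formulation of the paired
covariance test with a two-sided normal p; it is cross-checked in the
tests against both `pROC::roc.test` and a 10⁵-replicate paired
permutation oracle. Per-repetition AUROC is computed on the pooled
out-of-fold probabilities (one prediction per sample), the only
construction consistent with repeated leave-one-out. Forest importances
(mean decrease in impurity) are normalized to sum 1 per fitted forest,
averaged over folds and repetitions, and aggregated by map / feature
class / parcel with both group sums and group means reported — sums favor
numerous feature classes, means favor individually strong ones, and the
two answer different questions.

The hyperparameter score for choosing k (and n) over a candidate grid is
min × max × 1/variance of the observed AUROCs, variance clamped at
10⁻¹²; it rewards settings that are simultaneously good in the worst
case, good at best, and stable. The variance pools whatever collection of
AUROCs is passed in (repetitions, tracts, or both), exposed as data
rather than fixed policy.

## The synthetic phantom and what it can show

`generate_bundle` builds a bundle as a parametric centerline (line, arc
or helix) plus smooth per-streamline perpendicular offsets (constant +
linear + half-sine components with Gaussian coefficients, σ in mm), all
seeded. `generate_cohort` then builds per-subject FA/ADC/AD/RD-like maps
as smooth baseline (with a mild fixed spatial gradient) + seeded smooth
spatial noise + a class effect restricted to chosen parcels of a shared
voxel parcellation. Three effect types are supported:

* **mean**: adds `size` × noise-SD inside the target parcels — visible to
  any method;
* **variance**: scales the noise amplitude there;
* **texture**: replaces the noise with noise of `size`-times longer
  spatial correlation length at identical voxel mean and SD — invisible
  to per-parcel averages by construction, visible to texture features.
  This is precisely the mechanism that makes the central claim (richer
  features beat bare averages) testable without clinical data.

The phantom deliberately does **not** emulate dMRI physics, anatomical
tract shapes, registration error, partial-volume crowns, or
between-subject geometric variability (all subjects share one bundle
geometry and parcellation). Passing the synthetic-twin tests therefore
shows that the machinery detects the kinds of localized intensity and
texture differences it claims to detect — not that any particular
clinical effect size is recoverable from real cohorts.

**Study conditions used by the tests and the acceptance script** (chosen
once as a realistic desk-scale design): arc bundle of 50 streamlines,
σ = 0.8 mm dispersion, 22×22×12 grid at 1 mm; parcel count from the
adaptive rule at v = 5; cohorts of 20 + 20 subjects; noise SD 0.07 of
each map's natural scale with base correlation length 0.6 voxels; effects
of size 3 (in noise-SDs, or ×3 correlation length) in the two middle
parcels; selection k = 100; forests and repetitions exactly as in the
protocol above.

A caveat of this regime deserves emphasis: leave-one-out with supervised
feature selection refit inside every fold has a known *pessimistic* bias
on null data. Each training fold is imbalanced against the held-out
sample's class, and — more importantly — when thousands of candidate
features are screened on a few dozen training rows, the univariate step
preferentially keeps features on which the held-out sample happens to
resemble the opposite class (excluding it from its own class's training
mean makes exactly those features look most separating). Pooled
out-of-fold AUROC on effect-free data therefore falls *below* 0.5, mildly
for narrow feature sets (the 400-feature profile baseline stays near
chance) but severely for the full radiomic set at these sample sizes.
This is a property of the evaluation protocol at small n, not of the
features; it disappears as the subject count grows toward the scale of
real cohort studies, and it makes small-sample null AUROCs from this
protocol untrustworthy as calibration evidence in either direction.

## File-format conventions

World coordinates are RAS millimetres; voxel indices are 0-based; a world
point belongs to the voxel whose center is nearest under the inverse
affine. NIfTI I/O goes through RNifti (sform written with code 2). TCK
files store world mm directly; TRK stores corner-origin voxel-mm, which
is normalized through the header's voxel-to-RAS transform on read and
write, so both formats yield identical world coordinates (tested to
10⁻⁴ mm, the float32 storage limit). Label maps are written with the
smallest integer dtype that holds the label range. Feature tables are
CSV with a header row and the subject ID in the first column. Streamline
readers/writers are implemented natively because no installed R package
handles these formats.

## Known limitations

* Texture features are computed on the original maps only; filtered image
  banks (wavelet, Laplacian-of-Gaussian) are out of scope.
* The isosurface slightly underestimates volumes of very small or thin
  parcels (the smoothing radius is then comparable to the structure);
  voxel volume is exact and reported alongside.
* Along-tract correspondence across subjects relies on the shared
  centerline construction; no nonlinear along-tract registration is
  attempted.
* The correlation-pruning scan is O(p²) in memory (the full correlation
  matrix); with the default feature sizes this is a few hundred MB at
  most, but very large n·105 configurations may need chunking.
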