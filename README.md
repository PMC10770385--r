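# radtract: radiomic tractometry for tract-specific white matter analysis

Classic tractometry studies a white-matter tract by dividing it into `n`
parcels along its course and averaging a scalar parameter map (FA, ADC, AD,
RD) within each parcel — a profile of `n` numbers per map. That average
discards almost all of the image structure inside the tract, which limits
tractometry's value for subject-level predictive modelling.

`radtract` implements radiomic tractometry: the tract is parcellated **in
voxel space** (every envelope voxel is assigned to the nearest point of the
bundle centerline), and each parcel × parameter map is described by a
standardized set of **105 radiomics features** —

* 18 first-order intensity statistics,
* 14 shape descriptors (mesh volume/area, sphericity, diameters, axis
  lengths),
* 73 texture features from five gray-level matrix families
  (GLCM 22, GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14),

giving `4 · 105 · n` features per subject for four maps. The package also
provides the two classic baselines (static and centerline tractometry
profiles), the tensor scalar maps from eigenvalues
(ADC = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2,
FA = √(3/2)·‖λ−λ̄‖/‖λ‖), a training-only feature-selection cascade
(constant removal → Pearson |r| > 0.95 pruning → univariate F-based
k-best), and the full evaluation protocol: a random forest (100 trees,
depth 4) in ten differently seeded leave-one-out cross-validations, scored
by one-vs-rest AUROC, compared between methods with the paired DeLong test
(significant if any class's repetition-mean p < 0.05), and interpreted via
mean-decrease-in-impurity importances aggregated by map, feature class and
parcel.

A fully seeded synthetic phantom module (curved streamline bundles plus
parameter maps with localized mean-, variance- or texture-shift group
effects) makes every part of the pipeline testable without any imaging
data.

## Worked example

```r
library(radtract)

# a synthetic arc-shaped bundle of 50 streamlines in a 28x28x16 grid
bundle <- generate_bundle(phantom_spec(seed = 42))
tract  <- reorient_streamlines(bundle$tractogram)

# parcel count from the desired parcel thickness (v = 5 voxels)
n <- adaptive_parcel_count(list(tract), v = 5, seed = 42)
as.integer(n)
#> [1] 9

# voxel-space parcellation
parc <- parcellate_voxels(tract, bundle$reference, n)
parc
#> <parcellation> scheme=voxel, n=9 parcels (voxel space)

# a cohort of 20 + 20 subjects whose class difference is a pure texture
# change (spatial-noise correlation length x3 in parcels 4-5, equal means)
cohort <- generate_cohort(bundle, cohort_spec(
  n_per_class = c(A = 20L, B = 20L), n_parcels = n,
  effects = list(B = list(parcels = c(4, 5), type = "texture", size = 3)),
  seed = 101))

tabs <- cohort_feature_tables(bundle, cohort)
dim(tabs$radiomic)   # 40 subjects x 4*105*9 = 3780 features
#> [1]   40 3780

fit <- tract_evaluate(tabs$radiomic, cohort$meta$class, "classification",
                      model_config(seeds = 0:9), selection_config(k = 100))
fit
#> <tract_eval> classification, 40 samples, 10 repetitions
#>   mean AUROC_macro over repetitions: 1.0000
```

The per-parcel mean profiles of the same cohort hover around chance
(mean AUROC ≈ 0.47 in the run above) because the group effect is invisible
to parcel averages — the texture features are what separate the classes.
`aggregate_importance(fit)$by_parcel` then localizes the effect: the
injected parcels 4–5 carry the largest aggregated importance in every
repetition.

A thin command-line wrapper over the same functions is installed at
`inst/cli/radtract.R` with subcommands `maps`, `parcellate`, `profile`,
`features`, `select`, `fit`, `compare`, `importance`, `synth`; every run
writes a JSON manifest with the resolved parameters and input checksums.

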