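Package: radtract
Title: Radiomic Tractometry for Tract-Specific White Matter Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Along-tract analysis of white-matter fiber bundles that replaces
    classic per-parcel mean profiles with a standardized 105-feature radiomics
    set (first-order, shape, and five texture-matrix families) computed per
    tract parcel and scalar parameter map. Provides voxel-space tract
    parcellation via a bundle centerline, the two classic tractometry
    baselines (static and centerline point assignment), tensor-derived
    parameter maps (FA, ADC, AD, RD), a training-only feature-selection
    cascade (constant removal, correlation pruning, univariate k-best), a
    repeated leave-one-out random-forest evaluation protocol with one-vs-rest
    AUROC, paired DeLong ROC comparison, impurity-based importance
    aggregation, and a fully seeded synthetic fiber-bundle phantom generator
    for end-to-end validation without any imaging data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
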