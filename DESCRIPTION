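Package: neurorads
Title: Pre- and Postoperative CNS Tumor Segmentation and Standardized Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational backend for standardized reporting of central
    nervous system tumors from 3D magnetic resonance volumes. Provides a
    volumetric data model over NIfTI with the preprocessing chain used by
    patch-wise tumor segmentation models (isotropic resampling,
    skull-stripping, upper-quantile intensity clipping, normalization to
    [0, 1]), sliding-window 3D inference over pluggable voxel classifiers
    with probability fusion, affine patient-to-atlas registration with
    region-overlap location profiling, preoperative tumor feature reports
    (volume, laterality, multifocality, cortical and subcortical location
    profiles) and postoperative extent-of-resection reports, a three-tier
    segmentation evaluation suite (voxel-, patient-, and object-wise
    metrics with volume stratification and cross-fold pooling), and
    deterministic synthetic phantom, tumor, atlas, and cohort generators
    so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
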