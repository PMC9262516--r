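Package: myelinmap
Title: Longitudinal Intracortical Myelin Mapping from T1w/T2w MRI Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping relative intracortical myelin content from the
    ratio of T1-weighted to T2-weighted MRI intensities and for analysing its
    longitudinal change in two-group (healthy control vs. mild traumatic brain
    injury) cohorts. Implements voxelwise ratio computation restricted to gray
    matter, surface-based sampling of the ratio along transcortical segments
    joining corresponding white and pial mesh vertices (exact ray-voxel
    traversal with partial-voxel length weighting), regional aggregation over a
    cortical parcellation, and the longitudinal statistical procedure:
    confound-adjusted fractional change, linear rescaling to a common interscan
    interval, a mixed-effects model with per-subject random intercepts and
    slopes on interscan-interval deviations, Welch and paired t tests with
    family-wise correction, group-standardized z-score difference maps,
    regional vulnerability scores, and rank correlations with cognitive scores
    under dependence-aware false discovery rate control. A synthetic-cohort
    generator (spherical-shell cortex phantoms and longitudinal region tables
    with known ground truth) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
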