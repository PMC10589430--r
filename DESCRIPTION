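Package: strokepredict
Title: Prediction of Post-Stroke Motor Outcome in Mice from Lesion
    Topography and Early Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify experimental stroke lesions in atlas space and
    predict motor-functional outcome in the mouse middle cerebral artery
    occlusion (MCAO) model. Computes per-region lesion percentages
    ("segmented MRI"), edema-corrected lesion volumes, voxelwise incidence
    maps and volume-heterogeneity statistics from coregistered binary lesion
    masks; scores staircase skilled-reaching records into baseline-normalized
    subacute and residual deficit phases with mRS-like severity grades and
    recovery-transition matrices; and fits repeated-split bagged-tree
    regression models that compare lesion volume, lesion topography and the
    early deficit as outcome predictors, rank atlas regions by out-of-bag
    permutation importance, and select a minimal region subset via an
    incremental-inclusion prediction-error curve. A synthetic MCAO cohort
    generator with known ground truth supports end-to-end testing and
    parameter-recovery studies without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    randomForest,
    knitr
Config/testthat/edition: 3
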