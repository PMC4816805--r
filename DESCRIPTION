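Package: imageryvbm
Title: Structural and Representational Correlates of Auditory Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-differences neuroimaging pipeline linking
    self-reported vividness of auditory imagery to brain structure and
    function. Implements questionnaire scoring for auditory and visual
    imagery scales, voxel-based morphometry style mass-univariate
    regression of modulated gray-matter maps on behavioural scores with
    nuisance covariates, permutation-based cluster-level family-wise
    error correction and small-volume correction within spherical
    regions of interest, voxelwise one-way repeated-measures ANOVA
    across vocalization conditions, representational similarity
    analysis of condition t-maps within ROI spheres, and a
    spectral-rotation algorithm for rendering vocal sounds
    unintelligible. A synthetic-data generator with known ground truth
    supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
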