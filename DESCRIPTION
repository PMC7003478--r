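Package: parcbundle
Title: Gray-Matter-Parcellation-Constrained Whole-Brain Fiber Bundling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters whole-brain diffusion-MRI tractography streamlines into
    anatomically labeled fiber bundles connecting pairs of parcellated
    gray-matter regions. Implements a probabilistic bundle model that combines
    an isotropic Gaussian curve model with a distance-transform-based
    terminal-to-ROI projection likelihood, fitted by expectation-maximization
    for a single subject, and a groupwise extension that jointly estimates
    common bundle centroids and per-subject thin-plate-spline alignment to a
    common space. Includes bundle coherence and cross-subject consistency
    metrics, consistency-based bundle pruning, a fully ground-truthed
    synthetic phantom generator, and readers/writers for TCK/TRK streamline
    files and NIfTI label volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
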