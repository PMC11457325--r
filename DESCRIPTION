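Package: rtadapt
Title: Evaluation of Automated Online Adaptive Radiotherapy Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Session-wise geometric and dosimetric evaluation of automated
    versus clinically corrected contouring in online adaptive radiotherapy
    (oART) for bladder cancer with a simultaneous integrated boost. Provides
    voxel-grid structure and dose containers, planar-contour rasterization,
    segmentation agreement metrics (Dice, 95th-percentile Hausdorff distance,
    mean distance to agreement), dose-volume histogram based target-coverage
    metrics (V95 and dose spill outside the target), exact paired Wilcoxon
    signed-rank statistics with Bonferroni correction, stratification of
    coverage failures by influencer (bladder, rectum) volume change, and a
    reproducible synthetic pelvic phantom cohort generator for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
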