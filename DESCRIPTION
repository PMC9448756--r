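Package: choroid3d
Title: Three-Dimensional Choroidal Vessel Models and Morphometrics from
    OCT Volumes
Version: 0.1.0
Authors@R: person("Choroid3d", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructs three-dimensional choroidal vessel models (vessel
    volume, surface, and line models) from swept-source optical coherence
    tomography volume scans and computes eleven regional morphometric
    biomarkers of the choroidal vasculature, including choroidal volume,
    mean choroidal thickness, choroidal vascularity index, vessel length
    index, surface-to-volume ratio, and vessel diameter index. Vessels are
    enhanced with a 3D multiscale Hessian (Frangi-type) tubularity filter
    honouring anisotropic voxel spacing, binarized at a fixed 8-bit
    threshold, and restricted to a segmented choroid. A fovea-centred
    region-of-interest grid (1-mm centre circle plus four parafoveal
    quadrants of a 4.5-mm circle) localizes all measurements. A synthetic
    tube-phantom generator with analytic ground truth supports end-to-end
    validation, and cohort-level utilities provide Spearman correlation
    matrices, rank-sum comparisons, and two-cluster variable clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
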