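Package: normconn
Title: Normative Connectome Modeling and Single-Subject Anomaly Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a normative model of structural and functional brain
    connectivity from a healthy control cohort and flags per-edge 3-sigma
    anomalies in individual subjects. Functional correlation matrices are
    compared in the tangent space at the cohort's affine-invariant (Karcher)
    geometric mean; structural streamline counts are compared on a log scale.
    The one-third of edges with the highest between-subject variance in the
    control cohort is excluded before detection. Anomaly matrices are
    aggregated into per-region burden tables, cross-subject edge-frequency
    tables with hemisphere and anatomical-relationship annotation, and
    network-restricted submatrices. Includes a synthetic-cohort generator with
    planted edge-level effects and a simplified connectivity-driven,
    centroid-constrained voxel parcellation classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    MASS,
    xgboost
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
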