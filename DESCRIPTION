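Package: ensdyn
Title: Ensemble Dynamics Analysis of Protein C-Alpha Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residue-level analysis of protein conformational ensembles from
    molecular dynamics trajectories: Kabsch superposition and chain-pivot RMSD
    series, per-residue mean-square fluctuations, normalized dynamic
    cross-correlation maps (whole-trajectory and time-windowed), time-delayed
    orientational autocorrelations of virtual C-alpha backbone bond vectors,
    radius-seeded k-means clustering of conformations with an RMSD-to-centroid
    metric, joined-ensemble occupancy analysis, and principal component
    analysis with projections. Includes synthetic-trajectory generators with
    analytically known fluctuation covariance, Ornstein-Uhlenbeck temporal
    relaxation, rotational diffusion of bond vectors, rigid-body reorientation
    events and multi-basin ensembles, so every statistic can be validated
    against planted parameters; and a configurable, reproducible analysis
    pipeline with a manifest of checksummed outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
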