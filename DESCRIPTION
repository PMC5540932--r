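Package: lssrm
Title: Task-Induced Dopamine Release from Dynamic PET via a Linearized
    Extended Reference Tissue Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic modeling of task-induced striatal dopamine release from
    dynamic [11C]raclopride PET acquired with a bolus-plus-infusion protocol.
    Implements forward simulation and linear least-squares fitting of the
    simplified reference tissue model (SRTM) extended with a time-dependent
    gamma-variate activation term (LSSRM), computation of baseline and
    activation-phase binding potentials, edge-preserving masked Gaussian
    smoothing, motion screening, voxelwise parametric mapping, nonparametric
    permutation inference (paired sign-flip tests and a 2x2 group-by-time
    permutation ANOVA with variance smoothing and cluster-extent filtering),
    mixed-design behavioral ANOVAs with effect sizes, and a synthetic
    phantom-cohort generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    igraph,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
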