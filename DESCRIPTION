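Package: cryopipe
Title: Desk-Scale Single-Particle Cryo-EM Processing Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, desk-scale single-particle electron
    cryo-microscopy processing pipeline: whole-frame movie alignment with
    exposure weighting, contrast transfer function (CTF) determination
    with astigmatism and phase-plate support, matched-filter particle
    picking, maximum-likelihood 2D classification, 3D refinement with a
    matched-filter objective, Fourier-insertion 3D reconstruction with
    per-particle weighting, maximum-likelihood 3D classification with
    focused masks, ab-initio 3D reconstruction from random angles,
    automatic refinement with resolution-driven schedules, Fourier shell
    correlation resolution assessment with solvent correction, and map
    sharpening. Ships synthetic-data generators (phantom volumes,
    simulated particles, micrographs and drifting movies with known
    ground truth) so the whole pipeline is testable without external
    data. Images and volumes are read and written as MRC2014 files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
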