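Package: imsfold
Title: Native Ion-Mobility Conformational Landscapes and Structure-Based
    Folding Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of protein conformational landscapes measured by native
    ion-mobility mass spectrometry (IM-MS), together with coarse-grained
    structure-based modelling of the same proteins. Implements traveling-wave
    collision cross section (CCS) calibration against calibrant proteins,
    Gaussian deconvolution of CCS profiles into conformers, collision-induced
    unfolding (CIU) fingerprints with feature tracking and CIU50 transition
    voltages, Monte-Carlo projection-approximation CCS from atomic or
    C-alpha-bead structures, distance-based DFG-motif classification of
    protein kinases, and C-alpha Go-model construction with Langevin dynamics,
    native-contact, RMSF and RMSD-cutoff clustering analysis. A synthetic-data
    module generates every input the pipeline consumes with the statistical
    structure the analysis assumes, so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
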