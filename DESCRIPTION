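Package: netppi
Title: Physiophysiological Interaction Analysis of Resting-State fMRI Networks
Version: 0.1.0
Authors@R:
    person("netppi", "developers", email = "netppi@example.org", role = c("aut", "cre"))
Description: Tools for modelling modulatory (multiplicative) coupling between
    resting-state fMRI networks with physiophysiological interaction (PPI)
    regression. Provides canonical double-gamma hemodynamic response
    construction, regularized deconvolution of BOLD signals to the neural
    level, nuisance regression and discrete-cosine high-pass filtering,
    network-wise and voxel-wise PPI general linear models, group inference
    (Fisher-z correlation tables, one-sample t-tests, Bonferroni thresholds,
    random-field-theory cluster inference), a synthetic cohort generator with
    known ground-truth couplings for calibration and parameter-recovery
    studies, and minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
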