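Package: prepsaccade
Title: Simulation and Decoding of Preparatory-Set fMRI Signals for Pro- and
    Anti-Saccades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for event-related fMRI analysis of oculomotor preparatory
    set. Generates synthetic BOLD datasets for a delayed pro-/anti-saccade
    paradigm (randomised preparation durations, truncated-Poisson hold and
    inter-trial delays, class-specific multi-voxel response patterns),
    builds hemodynamic-response-convolved design matrices with
    discrete-cosine high-pass filtering, fits per-voxel general linear
    models with contrast t-maps and false-discovery-rate thresholding,
    computes region-of-interest univariate statistics (normalised percent
    signal change, paired t-tests, two-way repeated-measures ANOVA), and
    performs multi-voxel pattern decoding with a linear support vector
    machine under leave-one-run-out cross-validation, permutation-null
    calibration, voxel-subsampling accuracy curves and p-value-histogram
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
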