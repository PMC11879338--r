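Package: wpwsim
Title: Simulation and Sensitivity Analysis of Pre-Excited 12-Lead ECGs in
    Wolff-Parkinson-White Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of ventricular pre-excitation caused by
    antegrade accessory pathways on a synthetic biventricular anatomy with
    universal cardiac coordinates. Provides eikonal activation solves with a
    stylized action-potential template, an infinite-medium pseudo-ECG forward
    model assembling the standard 12-lead ECG, Latin-hypercube sweeps of
    accessory-pathway locations into an ECG database, AHA-style bullseye
    regionalization of exit sites, time-resolved variance-based sensitivity
    analysis via polynomial chaos expansion with sigma-weighted integrated
    Sobol indices, and ECG-feature-based accessory-pathway localization
    decision trees with an evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    signal,
    lhs,
    pracma,
    jsonlite,
    yaml,
    arrow
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessory.R'
    'activation.R'
    'anatomy.R'
    'database.R'
    'ecg.R'
    'localization.R'
    'pipeline.R'
    'regional.R'
    'sensitivity.R'
    'utils.R'
    'zenodo.R'
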