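Package: cardiomag
Title: Magnetocardiographic Source Imaging with Vectorcardiogram-Constrained
    Bayesian Solvers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of magnetocardiography (MCG) on
    synthetic cardiac geometry. Simulates per-node epicardial potential
    waveforms for a normal beat and three myocardial-infarction variants
    (increased R, ST elevation, increased T), builds Biot-Savart lead fields
    with either fixed radial dipole orientations or time-varying orientations
    derived from the vectorcardiogram (inverse Dower transform of an 8-lead
    ECG), and reconstructs epicardial sources with six solvers: Tikhonov L2,
    iteratively reweighted total-variation L1, Bayesian Gaussian regression
    with evidence-approximated hyperparameters, hierarchical variational-Bayes
    total variation, and dynamic-lead-field variants of the two Bayesian
    solvers that re-estimate dipole orientation each iteration. Includes the
    three evaluation statistics (epicardial RMSE, orientation angle of
    deviation, region of spread of the reconstructed abnormality) and a
    benchmark driver that sweeps disease cases, noise levels and seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
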