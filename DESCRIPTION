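Package: pepcr
Title: Projection-Based Kinetics Separation for Time-Resolved X-Ray Solution Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for time-resolved X-ray liquidography (TRXL)
    difference scattering data. Removes the kinetics of known signal components
    (solvent heating differentials, known intermediates) by orthogonal projection
    onto the complement of the "trivial" subspace (PEPC), extracts solute kinetics
    by singular value decomposition and global multi-exponential fitting with
    Gaussian instrument-response convolution, recovers species-associated
    difference scattering curves (SADS) under a kinetic model, corrects them for
    the projection-induced distortion, and reconstructs the solvent hydrodynamic
    response (temperature and density time traces). A synthetic forward model with
    full ground truth makes every stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
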