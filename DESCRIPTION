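Package: rdmlearn
Title: Machine-Learned One-Electron Reduced Density Matrices for
    Surrogate Electronic Structure and Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("rdmlearn", "developers", email = "rdmlearn@example.org",
           role = c("aut", "cre"))
Description: Learns the map from the electron-nuclear (external) potential
    matrix to the one-electron reduced density matrix (1-RDM) of a
    mean-field electronic-structure method with kernel ridge regression,
    purifies predictions to N-representability by aufbau occupation of the
    natural orbitals, and evaluates energies, one-electron properties and
    atomic forces from the predicted 1-RDM, including a correction for the
    nonvariational character of machine-learned density matrices. Training
    sets are generated by temperature-targeted normal-mode sampling around
    a relaxed geometry; a built-in restricted Hartree-Fock engine with
    Gaussian-type-orbital integrals supplies all ab initio labels, and an
    NVE velocity-Verlet integrator drives surrogate ab initio molecular
    dynamics with stability and trajectory-decoherence diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
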