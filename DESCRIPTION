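Package: qsar3d
Title: 3D-QSAR Modelling with Grid Molecular Fields, PLS and External
    Validation
Version: 0.1.0
Authors@R:
    person("QSAR3D", "Developers", email = "qsar3d@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional quantitative structure-activity
    relationship (3D-QSAR) modelling of small-molecule series.  Reads SDF
    (V2000) and MOL2 structures, assigns Gasteiger (PEOE) partial charges,
    rigidly superposes molecules on a common core (Kabsch), computes
    CoMFA-style Lennard-Jones/Coulomb and CoMSIA-style Gaussian similarity
    fields on a shared lattice, fits partial least squares models with
    leave-one-out cross-validation (including a SAMPLS-style kernel fast
    path), and implements a complete external-validation battery: r2pred,
    Golbraikh-Tropsha through-origin criteria, rm2 metrics, MAE-based
    criteria, Pareto ranking of candidate models and progressive
    y-scrambling.  Includes a synthetic-data generator with known sparse
    linear structure for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
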