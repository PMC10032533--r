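Package: magrheo
Title: Magnetic Microrheometry of 3D Culture Matrices with Bayesian
    Heterogeneity Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for magnetic-bead active microrheology of
    hydrogel 3D cell-culture matrices. Converts sinusoidal displacement
    tracks of matrix-embedded magnetic spheres into calibrated microscale
    viscoelasticity (absolute shear modulus, phase angle, Young's modulus)
    via generalized Stokes drag, and quantifies spatial heterogeneity with
    a Bayesian multilevel variance-components model that separates spatial
    variation from experimental design and heteroscedastic measurement
    noise. Includes a synthetic-data generator with known ground truth,
    Bayesian calibration of the volumetric force constant in a viscous
    fluid, leave-one-sphere-out predictive model comparison, and tidy
    CSV/YAML/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
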