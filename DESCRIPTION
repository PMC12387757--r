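Package: chiralflow
Title: Active Chiral Fluid Model and Quantification of Rotating Epithelial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the chiral cytoplasmic flow of a rotating epithelial
    cell as an axisymmetric active chiral Stokes problem driven by the force-
    and torque-dipole activity of a concentric dorsal actomyosin band, and
    quantifies rotation from experiment-shaped inputs. Includes an
    axisymmetric Taylor-Hood finite-element solver on a mapped triangulation
    of the meridional cell section, analytic activity (orientational order)
    fields, z-averaged angular-velocity profiling with dimensional
    calibration, particle image velocimetry (PIV) post-processing into
    azimuthal/radial components and radial profiles, cumulative nuclear
    rotation angles from two-landmark tracks, and seed-deterministic
    synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
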