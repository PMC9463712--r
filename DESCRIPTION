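Package: pfasim
Title: Electric-Field Modelling of Pulsed-Field Ablation Lesion Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational model of pulsed-field ablation (PFA) around a
    two-electrode catheter in a blood pool above a myocardial slab. Solves
    the steady-current volume-conductor equation on a structured voxel grid
    with a finite-volume scheme, thresholds the electric-field magnitude at
    an irreversible-electroporation (IRE) field strength, and extracts
    lesion depth as a function of applied voltage (100-2500 V) and
    catheter-tissue distance (0-5 mm). Includes a closed-form two-point-charge
    verification oracle, one-point conductivity-ratio calibration against
    in-vivo lesion-depth data, and drivers for voltage and contact sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
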