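Package: rm3d
Title: Design and Robustness Analysis of 3D Range-Modulators for Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing passive 3D range-modulators (ridge-filter-like
    pin arrays) for single-energy scanned proton beams, and for quantifying how
    robust the resulting dose distribution is to modulator misalignment.
    Includes an analytic Bragg-curve beam model with Highland multiple-scattering
    widths, non-negative least-squares optimization of spread-out Bragg peak
    weights, step and stepless pin contour generation, STL tessellation and
    rigid-body transforms of modulator meshes, a deterministic pencil-beam dose
    engine for a water phantom behind a PMMA pre-absorber, local gamma-index
    dose comparison, and a scenario runner reproducing shift/rotation
    misalignment studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
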