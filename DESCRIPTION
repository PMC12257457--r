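Package: beamforge
Title: Machine-Agnostic Convolution-Based Beam Modeling for Independent
    Monte Carlo Photon Dose Calculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic commissioning of a machine-agnostic photon beam model
    from water-phantom beam data (energy-spectrum slope tuning against the
    reference-field depth dose, electron-contamination weighting, off-axis
    scale map, and an output-factor-encoding collimator-scatter convolution
    kernel), plan and segment fluence calculation by convolution on the
    source-to-axis-distance plane, and a simplified voxel Monte Carlo
    photon/electron transport with static magnetic-field support for
    MR-guided machines. Includes a synthetic "golden machine" generator with
    known ground-truth parameters for closed-loop validation, gamma-index
    dose comparison, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
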