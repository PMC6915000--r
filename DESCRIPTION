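Package: gaitsf
Title: Time-Continuous Symmetry Function Analysis of Bilateral Gait Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bilateral gait asymmetry with the time-continuous
    symmetry function SF(t), the percentage difference between the two sides'
    joint-angle curves normalised by the mean of their ranges of motion.
    Includes time normalisation of measured gait cycles to a canonical
    101-point (1% cycle-time) grid via local Lagrange interpolation, curve
    parameterisation (peak values, peak times, range of motion), localisation
    of asymmetry by Perry gait phase, ensemble averaging and side/group
    statistics, a synthetic bilateral-gait simulator with controllable
    asymmetry mechanisms for validation, long-format CSV input/output, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
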