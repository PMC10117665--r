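Package: dropletTrap
Title: Zebrafish Mobility Quantification in a Vibrating-Droplet Flow Trap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and analysis for quantifying larval zebrafish mobility in a
    recirculating-flow droplet trap. Provides parametric in-droplet flow fields
    with recirculation-cell classification, slender-body viscous torque and
    orientation equilibria, an overdamped active-swimmer orientation simulator
    with activity-parameter recovery, synthetic fluorescence scene rendering
    with centroid detection, optimal frame linking and particle-tracking
    velocimetry, and the angle-based mobility statistics (circular summaries,
    source-deviation angle, chance-alignment probability, mean squared
    displacement, mobility classification and recovery trends).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    clue,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
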