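Package: stakitt
Title: EPID-Based Multileaf Collimator Positional Quality Assurance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a picket-fence-style multileaf collimator (MLC)
    positional test ("stakitt") for linear accelerators.  Six 2 cm wide
    MLC-defined sub-fields plus outer comb patterns are imaged on the
    electronic portal imaging device (EPID); individual leaf tips are
    measured at sub-pixel precision from 50% penumbra crossings along
    per-leaf trajectories and referenced to the collimator rotation axis,
    giving absolute per-leaf position deviations and leaf-pair gap
    deviations.  Includes beam central-axis determination from collimator
    90/270 jaw field pairs, gantry-sag correction from cone-arc cine
    frames, a synthetic EPID image simulator with known ground truth for
    end-to-end validation, and repeatability, sensitivity and backlash
    experiment harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
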