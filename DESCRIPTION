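Package: pitchsense
Title: Energetics of Body Pitch During Electrosensory Prey Search
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Models the trade-off between swimming efficiency and sensory
    scanning in gliding electrosensory fish. Implements a cuboidal-sensorium
    projection geometry, a power-law-in-pitch and quadratic-in-speed drag
    model fitted to tow-tank force measurements, a ribbon-fin thrust
    correlation with surge and heave components, and an
    energy-per-prey-encounter model with counterfactual scenarios in which
    the projected sensorium area or the body drag is held at its neutral-pitch
    value. Includes a seeded synthetic tow-measurement generator for
    end-to-end parameter-recovery studies and a reproduction driver that
    writes all derived tables and a machine-readable summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
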