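Package: kineat
Title: Food-Item Classification from Wrist-Worn Accelerometer Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for recognising which food item is being eaten
    from raw 5 Hz triaxial acceleration recorded by wrist-worn smartwatches
    during meals. Derives seven per-sample kinetic variables (x/y/z
    acceleration, pitch, roll, power and gravity-purged total energy),
    synchronises watch and camera clocks via hand-clap transients, fuses two
    video annotators' eating intervals into united and intersected label sets,
    summarises sliding windows into slope-based Information Units, and fits
    stratified random-forest classifiers with cross-validated mtry selection,
    out-of-bag one-vs-all sensitivity and specificity, and Gini importance
    scaled to 0-100. Includes a seeded synthetic meal simulator with a
    controllable food-separability dial so the full pipeline is testable
    without access to raw study recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
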