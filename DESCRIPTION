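Package: ferropaper
Title: Smartphone Quantification of Iron on Paper-Based Ferrozine Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies iron fortificants in food from photographs of
    paper-based Ferrozine assay spots. Converts RGB images to inverted
    8-bit grayscale, measures mean pixel intensity inside a circular
    detection zone, fits a log10-linear intensity-concentration
    calibration, and inverts it to report iron concentration in the food
    with dilution correction. Includes an analytical-validation toolbox
    (limit of detection from blank + 3 sigma, working range, sensitivity,
    apparent spike recovery, interference bias, within-day replication CV,
    and Bland-Altman method comparison against a reference method), a
    synthetic spot and dataset generator for testing, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
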