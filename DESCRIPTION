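Package: structome
Title: Quantitative Structome Analysis of Bacterial Cells from Serial
    Ultrathin Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell morphometry ("structome analysis") of rod-shaped
    bacteria from serial ultrathin transmission electron microscopy
    sections. Per-section membrane perimeters, cross-sectional areas and
    ribosome counts are turned into whole-cell profiles: length, outer- and
    plasma-membrane diameters, trapezoid-reconstructed surface areas,
    Cavalieri-type compartment volumes (whole cell, membranes, periplasm,
    cytoplasm) and cytoplasmic ribosome density per 0.1 fl. Includes a
    synthetic spherocylinder cell generator with analytic ground truth for
    validating every estimator, summary statistics and two-sample t-tests
    (including from published summary statistics alone), one-way ANOVA for
    between-species comparisons, and an exponential calibration linking
    ribosome density to population doubling time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
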