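Package: thermoface
Title: Facial Thermography Stress-State Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying physiological stress states from facial
    infrared thermograms. Decodes grayscale thermal images to temperature
    matrices over a known scale, locates five facial regions of interest
    (nose, cheeks, forehead, chin) from 68-point landmark sets using
    face-box-scaled rectangle geometry, extracts per-region mean skin
    temperatures, summarises them per state with Friedman repeated-measures
    tests, and trains a radial-basis-function support vector machine to
    label frames as baseline, stress or relax. A seeded synthetic
    thermal-face generator emulates a short Trier Social Stress Test
    session so every stage of the pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
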