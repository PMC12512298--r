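Package: anolechroma
Title: Color-Morph Extraction and Seasonal-Thermal Modeling for Anole Field Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive green/brown color-morph states of Anolis
    carolinensis from segmented field photographs and to model their seasonal
    and thermal drivers. Includes dominant-color extraction by k-means
    quantization of masked pixels, RGB threshold classification
    (green, brown, unclear), background-ring greenness indices for
    crypsis tests, hourly temperature reconstruction from daily
    minima/maxima via a sine/log-decay diel model, cyclic-spline binomial
    GAMs of phenology, season-by-temperature logistic regression with AIC
    model selection, and a synthetic-data generator with known ground truth
    that makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    png,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
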