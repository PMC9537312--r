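Package: glenocard
Title: Comparison-Card and Best-Fit-Circle Quantification of Glenoid Bone Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying anterior glenoid bone defects on 2-D
    en-face views. Solves the equal-area partition of a circle to generate a
    transparent comparison-card overlay (40 grids of 2.5% each for the
    default 50 mm card), measures defect percentage by grid counting with a
    half-grid tolerance rule and its quantization-error bound, implements
    the Sugaya best-fit-circle defect ratio D = A/S with severity
    classification, generates synthetic glenoid phantoms with known true
    defect fraction, and validates method agreement with intraclass
    correlation, Bland-Altman analysis and across-observer ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
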