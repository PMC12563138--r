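Package: breakeven
Title: Break-Even Point Estimation for Bone Graft Substitution Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the break-even point of graft substitution in bone
    regeneration studies: the healing time and tissue fraction at which newly
    formed bone equals residual graft material, obtained by intersecting linear
    trends fitted between histomorphometric time points. Includes segment
    selection for multi-timepoint series, classification of extrapolation
    validity, dimension-loss computation, bootstrap uncertainty from
    animal-level replicates, and a nonlinear graft-substitution simulator for
    characterizing the bias of the linear estimator. Ships a worked dataset of
    six biomaterials from four rabbit sinus floor elevation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
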