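Package: lineupSDT
Title: Signal Detection Models for Eyewitness Lineups with Base-Rate
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits the equal-variance signal detection theory (SDT) model for
    simultaneous eyewitness lineups to collapsed identification data in which
    the guilt or innocence of the suspect is unknown, estimating the base rate
    of guilty suspects alongside memory strength and confidence criteria by
    G-squared minimization. Computes posterior probability of guilt (PPG),
    diagnosticity ratios, and confidence-accuracy calibration curves, and
    provides a full evaluation toolkit: a max-rule trial simulator, bootstrap
    base-rate studies, base-rate sensitivity profiling, parametric bootstrap,
    parameter-recovery simulations, and an unequal-variance misspecification
    study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
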