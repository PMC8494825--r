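Package: dielkit
Title: Diel Activity Analysis for Camera-Trap Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for temporal (diel) activity patterns of
    animals recorded by camera traps. Collapses raw photo records into
    independent detection events, fits circular kernel densities with a von
    Mises kernel and plug-in bandwidth, estimates activity levels with
    bootstrap uncertainty, classifies species as nocturnal, diurnal,
    crepuscular or cathemeral via Poisson mixed models or Manly design-I
    selection ratios depending on sample size, and quantifies pairwise
    temporal overlap with the nonparametric Dhat1 and Dhat4 coefficients and
    smoothed-bootstrap confidence intervals. Includes a synthetic
    camera-trap study generator with known ground truth so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    multcomp,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
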