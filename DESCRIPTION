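Package: pestavision
Title: Visual Ecology of Bioluminescent Light-Organ Patterns in Deep-Sea Shrimps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether deep-sea sergestid shrimps could
    recognise each other by the arrangement of their bioluminescent light
    organs (organs of Pesta). The package fits allometric eye-to-body
    scaling with ANCOVA tests for sexual dimorphism, computes maximum
    sighting distances of a bioluminescent point source from a Lambert-W
    closed form of the photon-budget equation (with an independent
    bisection oracle), estimates compound-eye spatial resolution
    (interommatidial and minimum resolvable angles, least-squares circle
    fits of eye contours, one-way ANOVA with Tukey HSD), renders
    light-organ patterns through an acuity-limited modulation-transfer
    low-pass filter, and scores pairwise pattern discriminability against
    a self-noise null. Seeded generators provide every synthetic input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
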