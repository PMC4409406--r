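Package: macromove
Title: Movement-Path Analysis for Video-Tracked Benthic Macroinvertebrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 1-Hz video-tracking data of benthic
    macroinvertebrates (e.g. the isopod Asellus aquaticus and the amphipod
    Gammarus pulex) moving in a 1 m2 arena. Provides a correlated random walk
    simulator with move/rest bouts and exponential or heavy-tailed step
    lengths, synthetic frame rendering and marker-blob tracking with
    noise-floor calibration, margin and gap based path segmentation, step
    length, turning angle, resting and stop-rate metrics, divider-method
    fractal dimension estimation of path tortuosity, circular statistics
    including the Watson-Wheeler test, and a treatment-comparison scheme
    (Welch/ANOVA, Wilcoxon/Kruskal-Wallis, Watson-Wheeler) with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
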