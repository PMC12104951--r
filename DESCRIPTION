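Package: bowmetrics
Title: Bowman's Layer Thickness from Simulated Ultra-High-Resolution Corneal OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ultra-high axial resolution corneal OCT B-scan captures of a
    layered cornea with known interface geometry, and implements the full analysis
    chain used to measure central Bowman's layer thickness (BT): low-signal frame
    screening, axial-only cross-correlation alignment and averaging, iterative
    graph-search segmentation of the tear-film, epithelium-Bowman and Bowman-stroma
    interfaces with path blocking, quality grading and weighting, quasi-point
    thickness extraction over a 450 micrometre window, and cohort statistics
    (group summaries, ANOVA with Tukey post hoc, BT~CCT regression and BT/CCT
    ratio independence analysis) on synthetic cohorts of healthy, keratoconus and
    corneal dystrophy eyes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
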