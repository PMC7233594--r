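Package: lcshift
Title: Optic Nerve Head Vascular Trunk Geometry and the Hemisphere of
    Glaucomatous Visual Field Onset
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying lamina cribrosa shift in myopic high-tension
    glaucoma through the position of the central retinal vascular trunk within
    the Bruch's membrane opening (BMO). Implements the planar landmark
    geometry (angular deviation, shift index, beta-zone parapapillary atrophy
    angle, obliqueness, lamina cribrosa depth), the Humphrey 24-2
    pattern-deviation cluster rule with longitudinal initial- and
    final-hemisphere determination, a synthetic cohort generator with
    configurable ground truth, and the statistical stage: contingency tests,
    one-way ANOVA from summary statistics with Scheffe post hoc tests,
    logistic risk-factor screening fitted by iteratively reweighted least
    squares, and a simplified conditional inference tree based on permutation
    tests. A pipeline orchestrator assembles per-eye measurements into a
    cohort table and reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
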