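Package: rocvs
Title: ROC, BEDROC and Enrichment Analysis for Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation of ranked virtual-screening results from plain-text
    score tables. Computes receiver operating characteristic (ROC) curves
    with trapezoidal area under the curve (AUC) and the Hanley-McNeil
    nonparametric standard error, the Boltzmann-enhanced discrimination of
    ROC (BEDROC) early-recognition metric at arbitrary alpha, and enrichment
    factors in the two conventions common in the docking literature (top-X
    percent of the ranked list, and actives recovered before X percent of
    the decoys). Renders publication-quality linear or semi-logarithmic ROC
    figures and ships a command-line interface for batch evaluation of one
    or more score files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
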