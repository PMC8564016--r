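Package: ffram
Title: Analytical Fractional Flow Reserve from Coronary Tree Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes non-invasive fractional flow reserve (FFR) for
    coronary artery stenoses with a closed-form analytical model rather
    than computational fluid dynamics. A reconstructed coronary tree
    (per-branch centerline arc length and lumen-area profiles) and scalar
    patient physiology (left-ventricular mass, cuff pressures) yield
    resting flow, a diameter-scaling-law allocation over the tree, a
    stenosis-dependent hyperemic multiplier, and per-lesion pressure
    drops decomposed into contracting, throat, and expanding segments
    (viscous plus contraction/expansion losses). Includes lesion
    detection and anatomical parameterization on lumen-area profiles,
    generators for synthetic stenosed vessels, bifurcating trees and
    virtual cohorts, and diagnostic-evaluation statistics (2x2 metrics,
    ROC AUC, DeLong paired test, Bland-Altman agreement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
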