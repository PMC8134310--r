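Package: biopsynav
Title: Navigation Accuracy Evaluation for Template-Guided Transperineal Prostate Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry and statistics for evaluating the targeting accuracy of
    MR-guided transperineal prostate biopsy performed through a fiducial-
    calibrated grid template. Provides rigid point-set registration of
    template fiducials and frame landmarks, virtual-grid target planning with
    cannula depth and projected-core computation, extrapolation of
    ground-truth biopsy cores from observer needle picks, two geometric error
    metrics (target to core center, target to core trajectory) with summary
    statistics and interobserver variability, and a seeded synthetic phantom
    experiment generator so the complete accuracy study can be reproduced
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
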