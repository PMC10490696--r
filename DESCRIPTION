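Package: wetshift
Title: Wetland Land-Cover Change Accounting and Machine-Learning Driver Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-epoch categorical land-cover change accounting (single land-use
    dynamic index, class-to-class area transfer matrices, gridded transformation
    intensity on a 10 km analysis grid), spatially balanced sampling of change
    cells, and driver attribution for natural-wetland change via gradient-boosted
    regression whose depth and tree-count hyperparameters are tuned by a sparrow
    search algorithm (SSA), reporting per-driver percentage contributions.
    Includes a driver-modulated Markov landscape simulator so that attribution can
    be validated against known ground truth, and a reference area series for the
    Northeast China Plain for worked examples.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    tiff,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
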