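Package: mycocarbon
Title: Linking Soil Microbiome Composition to Forest Carbon Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline connecting soil microbiome surveys
    (16S and ITS amplicon OTU tables) to forest carbon storage measured
    on permanent inventory plots. Provides stand-level tree growth and
    live-biomass carbon estimation by allometric bootstrap upscaling,
    soil carbon and nitrogen stock calculation, OTU-table quality
    control, rarefaction and diversity metrics, Bray-Curtis ordination
    (PCoA) with permutation-based environmental vector and factor
    fitting, distance-based redundancy analysis, negative-binomial Wald
    indicator-species analysis against continuous carbon covariates,
    and additive-model regression of carbon outcomes on environmental
    covariates plus single microbiome predictors with collinearity
    diagnostics. A calibrated synthetic-study generator makes the whole
    chain runnable and testable without access to restricted inventory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr
Config/testthat/edition: 3
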