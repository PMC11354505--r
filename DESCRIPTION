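Package: octvol
Title: OCT B-Scan Volumetry of Retinal Entities with Agreement Statistics
Version: 0.1.0
Authors@R:
    person("octvol", "maintainers", email = "octvol@example.org",
           role = c("aut", "cre"))
Description: Measures volumes of arbitrary retinal entities from manual
    contour annotations on optical coherence tomography (OCT) B-scan
    rasters: per-scan cross-sectional areas (shoelace formula) are summed
    and multiplied by the inter-scan distance, optionally restricted to a
    1000-micron foveal circle via per-scan chord clipping. Includes the
    full agreement-validation toolkit for such measurements (Bland-Altman
    bias, coefficient of repeatability, limits of agreement with
    confidence intervals, and power for agreement studies), an analytic
    phantom generator with simulated observers for validation without
    clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
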