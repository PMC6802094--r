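Package: baciveg
Title: Before-After-Control-Impact Evaluation of Vegetation Condition in
    Protected Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating the effect of protection elevation on forest
    vegetation condition with a before-after-control-impact (BACI) matched-pair
    design on satellite vegetation-index time series. Computes the enhanced
    vegetation index (EVI) and normalized difference infrared index (NDII) from
    masked multiband surface-reflectance stacks, builds annual brownest and
    driest robust-minimum composites with fractional-year date-stamps,
    estimates per-pixel epoch-wise trends with the Theil-Sen (or Siegel
    repeated-medians) estimator, classifies pixel condition and condition
    change from the slope signs, summarizes protected-area composition, and
    matches impact reserves to control sanctuaries under area, state and
    rainfall constraints. Includes a synthetic scene generator with known
    ground-truth trend structure so the full pipeline is testable without
    satellite downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
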