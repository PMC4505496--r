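Package: tubequant
Title: Quantitative Image Analysis of Membrane Tube Fluorescence Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein recruitment and clathrin assembly on
    supported membrane tube (SMrT) templates imaged by time-lapse fluorescence
    microscopy. Implements ratiometric curvature-sorting densitometry on budded
    tube templates, one-site binding fits of titration data, kymograph-based
    single-event clathrin assembly kinetics (dead-time estimation, per-pixel
    plateau-plus-exponential fits, R-squared filtering, contiguous-event
    deduplication, and log-space time-constant summaries), clathrin foci
    detection and linear density estimation, and coating-layer correction of
    electron-microscopy diameter measurements. A forward simulator generates
    multi-channel synthetic movies of budded tube fields with known ground
    truth (geometry, curvature enrichment, binding affinity, assembly
    kinetics) so that every analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
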