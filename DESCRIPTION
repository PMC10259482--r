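Package: strainsite
Title: Quantification of Protein Recruitment to Stress Fiber Strain Sites
    and Stereocilia Actin Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying force-dependent protein
    recruitment to laser-induced stress fiber strain sites from two-channel
    live-cell time-lapse microscopy: flat-field and photobleach correction,
    whole-image sub-pixel translation registration by phase cross-correlation,
    reference-image relative differencing, brightest-fraction masking,
    recruitment traces and spatial recruitment-probability maps. Also
    implements stereocilia-side statistics: line-scan gap enrichment ratios
    and per-organ aggregation of gap frequency, dead-cell percentage, and
    stereocilia counts. Includes a ground-truthed synthetic microscopy data
    generator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
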