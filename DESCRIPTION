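Package: slideOverview
Title: Patient-Level Overview Figures from Pyramidal Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns pyramidal whole-slide histology images into patient-level
    overview figures with region-of-interest insets and physically correct,
    micron-calibrated scale bars, plus a cohort-summary stage for
    immunophenotype tables from xenograft quality-control programs. Includes
    a deterministic synthetic-slide generator with machine-readable ground
    truth, semi-automatic tissue bounding-box detection on thumbnails, and a
    declarative multi-panel figure composer with JSON provenance manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
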