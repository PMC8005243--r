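Package: grayzonePET
Title: Dual-Cutoff Quantification of Early Amyloid-Beta Deposition on Amyloid PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting early amyloid-beta deposition from regional
    amyloid PET SUVR tables: derivation of an early (mean + 2 SD of young
    controls) and an established (ROC/Youden) cutoff per region on the SUVR
    and centiloid scales, three-category gray-zone classification, centiloid
    calibration and validation, delta-SUVR topographic staging against the
    half-maximal carrying capacity of a logistic accumulation trajectory,
    per-subject longitudinal accumulation rates with group tests, progression
    and tau-association summaries, visual-versus-quantitative concordance,
    and a seeded synthetic-cohort generator emulating the multi-dataset
    group structure such studies assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
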