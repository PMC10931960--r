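Package: pelvitilt
Title: Pelvic Tilt Measurement and Annotation-Adequacy Analysis from
    Radiographic Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for measuring sagittal pelvic tilt from multi-annotator
    radiographic landmark coordinates under the anatomical (anterior pelvic
    plane) and mechanical (femoral-head centre to sacral-plate midpoint)
    definitions, with the femoral-head centre either estimated directly or
    calculated from annotated bone contours via circumcentre geometry.
    Includes majority-rule adjudication of multi-assessor annotation-adequacy
    reviews, comparison statistics between the full and the adequate
    measurement datasets (Pearson correlation, mean and maximum absolute
    difference, limits of agreement, paired t-tests, intraclass correlation
    against a reference series), and a seeded synthetic annotation-study
    generator with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
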