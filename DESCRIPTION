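Package: cobbangle
Title: Automatic Cobb-Angle Measurement from Vertebral Corner Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic Cobb-angle measurement for coronal spine
    radiographs annotated with four corner keypoints per vertebra: moving
    least squares centerline fitting, polynomial second-derivative
    inflection analysis, per-segment exhaustive endplate-line angle search
    with a 5-degree floor, and major/minor curve reporting with severity
    grading. Also provides the reliability statistics used in
    method-comparison studies of Cobb-angle measurement (ICC(2,1) with
    consistency bands, Bland-Altman limits of agreement, mean absolute
    error, accuracy rate, end-vertebra offset tables) and a parametric
    synthetic-spine generator with analytically known curve angles for
    validation without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
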