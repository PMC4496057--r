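Package: reefpoint
Title: Point Annotation of Benthic Survey Images with Semi- and
    Fully-Automated Operational Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for percent-cover estimation of benthic substrata from
    random point annotations of survey photoquadrats. Provides a patch-based
    texture and color classifier with one-versus-rest linear maximum-margin
    scoring, three deployment modes for automation (score-thresholded
    deferral to a human annotator, confusion-matrix-inverted cover
    correction, and top-k label suggestion), a full annotator-agreement and
    cover-error evaluation suite (Cohen's kappa, group kappa, confusion
    matrices, permutation tests and percentile-t bootstrap intervals), and
    synthetic generators for textured mosaic imagery, simulated annotators
    and simulated classifier scores so the whole pipeline can be exercised
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    MASS,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
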