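Package: metacontrol
Title: Meta-Analysis of Control Arms from Large-Animal Myocardial
    Infarction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analysing control-arm data from large-animal
    myocardial infarction experiments. Implements random-effects pooling of
    raw-mean percentage outcomes (infarct size as a fraction of the area at
    risk or of the left ventricle, and ejection fraction) with restricted
    maximum likelihood estimation of between-study variance, univariable and
    multivariable meta-regression on study-design moderators with post-hoc
    Wald contrasts, proportion meta-analysis of peri- and post-procedural
    mortality with a sequential-proportion combination rule and an explicit
    inverse-root-n weighting convention, and prediction of expected outcomes
    for named experimental designs. A synthetic study-level data generator
    with known ground truth supports simulation-based validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    metafor,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
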