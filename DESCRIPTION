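Package: bonemed
Title: Mediated Multilevel Models of Muscle Strength and Bone Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the hierarchical mediated regression analysis used to
    study the functional model of bone development in growing children: bone
    speed-of-sound and muscle-strength equations fitted as random-intercept
    linear mixed models by maximum likelihood, direct/indirect/total effect
    decompositions with delta-method (Sobel) standard errors, Chow-type Wald
    tests of coefficient equality between strata, and a calibrated
    mixed-longitudinal synthetic cohort generator so every stage of the
    pipeline can be exercised without restricted participant data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
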