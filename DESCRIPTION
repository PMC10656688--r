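Package: autobirads
Title: Automated BI-RADS Assessment of Breast Ultrasound Sweep Videos
Version: 0.1.0
Authors@R: person("Auto", "BIRADS Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for rule-based BI-RADS assessment of breast ultrasound
    sweep videos. Selects lesion-bearing frames and segments the lesion with a
    classical dark-object pipeline, extracts the six ACR BI-RADS lexicon
    categories (shape, orientation, margin, echo pattern, posterior acoustic
    features, calcification) per frame by morphological image processing, fuses
    the per-frame labels across the sweep with frame-proportion thresholds and
    a weighted rank-threshold score table into a BI-RADS category (2-5) and a
    benign/malignant call, and evaluates performance and reader agreement
    (DeLong AUC comparison, Cohen's kappa, McNemar, percent agreement). Ships a
    speckle phantom generator that simulates a linear-transducer sweep through
    a lesion with independently controllable ground truth for every lexicon
    level, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
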