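Package: tvvloop
Title: T-Vector-Velocity Trajectory Quantiles for Drug-Induced
    Repolarization Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes T-vector-velocity (TVV) trajectory quantile biomarkers
    (Tr10-Tr100) from annotated 12-lead ECGs via vectorcardiographic
    reconstruction, heart-rate-corrects them with linear mixed models,
    derives placebo-corrected exposure-response drug-effect profiles, and
    discriminates pure hERG/iKr potassium-channel block from multichannel
    block by logistic regression with stratified-bootstrap AUC confidence
    intervals. Includes a synthetic crossover-study generator with known
    ground-truth effect profiles so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    yaml,
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
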