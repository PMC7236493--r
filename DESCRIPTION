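Package: censvm
Title: Support Vector Machine Classification for Right-Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary-classification support vector machines for right-censored
    time-to-event data. Censored observations are weighted by their Kaplan-Meier
    conditional survival probability (or proportional follow-up time) and fed to
    one of four convex-QP trainers: a per-sample weighted SVM, a probabilistic
    SVM with uncertain class membership, an SVM using censoring information as
    privileged information (LUPI), and a semi-supervised SVM with local
    invariances (gradient and local-averaging RKHS representers of the Gaussian
    kernel). Cox proportional hazards and kernel Cox regression comparators, a
    Gompertz/frailty survival simulation harness with calibrated censoring, and
    a two-step tuning/testing and nested cross-validation evaluation suite are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    kernlab,
    MASS,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    e1071,
    pROC
Config/testthat/edition: 3
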