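Package: habitdecay
Title: Idiographic and Multilevel Modelling of Habit Decay from Daily Diary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intensive longitudinal (daily diary) measurements
    of habit strength while people attempt to break a habit. Provides a seeded
    synthetic diary-cohort generator; preprocessing of raw e-diary responses
    (after-midnight recoding, duplicate averaging, SRBAI scoring, singleton
    imputation, retention filtering); person-specific fitting of six trajectory
    families (constant, linear, quadratic, cubic, asymptotic, logistic) with BIC
    model selection; a four-step validity gate (decreasing trend, leave-one-out
    selection stability, RMSE cut-off, missing-gap cut-off); three estimators of
    the time for habit decay to stabilize; and group-level mixed models
    (variance decomposition, cubic growth models with behavioural-group
    contrasts, and a two-stage asymptotic multilevel estimator).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
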