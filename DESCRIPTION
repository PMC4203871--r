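Package: icuscore
Title: Naive Bayes Scoring Systems for Prolonged Intensive-Care Stay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design, validation, updating and application of additive
    scoring systems for predicting prolonged intensive-care-unit stay
    (length of stay of 120 hours or more) after cardiac surgery. The score
    is a naive-Bayes decision rule over discretized clinical variables:
    each category of each predictor contributes a log-likelihood-ratio
    (weight-of-evidence) weight estimated from class-conditional counts, so
    the whole model is defined by descriptive tables that can be updated
    incrementally by adding or removing patient records. Includes
    univariate odds-ratio screening at a fixed confidence level, forward
    stepwise feature selection maximizing the area under the ROC curve with
    a windowed stopping rule, five-fold cross-validation, bias-corrected and
    accelerated (BCa) bootstrap confidence intervals for the AUC, and a
    synthetic cardiac-surgery cohort generator with known ground truth for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC, boot, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
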