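Package: xaudit
Title: Accuracy and Reliability Audits for Free-Text Clinical Report Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audit pipeline for free-text clinical report classification.
    Generates labeled synthetic report corpora with planted class-indicative,
    context-dependent and spurious vocabulary; normalizes raw report text into
    token sequences; trains and evaluates classifiers (majority baseline,
    TF-IDF + multinomial logistic regression, a differentiable embedding-bag
    network) under leave-one-out and prospective hold-out protocols with
    random oversampling for class imbalance; explains predictions with LIME,
    Kernel SHAP and Integrated Gradients; and verifies explanations both
    technically (fidelity and deletion checks) and against expert word lists
    (normalized importance apportioned to valid, perhaps-valid, unknown and
    invalid categories), with Cohen's kappa for annotation agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
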