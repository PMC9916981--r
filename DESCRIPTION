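Package: hka
Title: Hypothesis Kernel Analysis for Action-Unit Models of Facial
    Expression Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns qualitative hypotheses that map facial Action Units (AUs)
    to emotion categories into predictive classifiers and evaluates them
    against forced-choice categorization behavior. A hypothesis and each
    stimulus are embedded in a common 33-dimensional AU amplitude space; a
    kernel (cosine by default) scores their similarity, a softmax converts
    scores to category probabilities, and one-vs-rest AUROC measures
    predictive performance per participant and category. The package also
    estimates a categorical noise ceiling from between-participant response
    inconsistency on repeated stimuli, probes models causally by AU ablation,
    constructs optimized culture-accented models from performance-critical
    and performance-detrimental AUs, fits data-driven models via
    point-biserial correlations with leave-one-participant-out
    cross-validation, and ships a synthetic-behavior simulator so the full
    prediction-explanation-exploration cycle runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
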