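Package: rerx
Title: Recursive Rule Extraction from Neural Networks for Interpretable
    Diabetes Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts interpretable if-then diagnostic rules from trained
    feed-forward neural networks by the continuous recursive-rule
    extraction (Re-RX) procedure: a single-hidden-layer network is fitted
    with a weight penalty, irrelevant input attributes are pruned by
    aggregate weight magnitude, a C4.5 decision tree (gain-ratio splits,
    pessimistic pruning) is induced on the network-consistent samples,
    and high-error well-supported rules are recursively subdivided.
    Includes a class-conditional synthetic cohort generator emulating a
    national health-survey diabetes/prediabetes dataset, a rule-set
    parser/evaluator with a shipped 15-rule reference model for
    prediabetes-versus-diabetes discrimination (including urinary
    albumin-to-creatinine ratio cut-offs), and a repeated stratified
    cross-validation harness reporting accuracy, rule counts and AUC-ROC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
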