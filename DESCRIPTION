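Package: inquirydx
Title: Reinforcement Learning for Staged Diagnostic Inquiry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An actor-critic agent that learns to conduct staged clinical
    inquiry: it sequentially recommends symptom and history questions,
    physical-examination checks and auxiliary-examination panels, then
    terminates with a diagnosis. The actor nests a product-of-experts
    variational autoencoder over partially observed feature vectors; training
    uses proximal policy optimization with rewards that combine
    diagnostic-information gain (KL divergence to the reference diagnosis)
    with penalties for skipping items a physician asked. Includes a synthetic
    electronic-health-record world generator with disease-conditional feature
    emission and simulated physician inquiry sequences, a supervised
    diagnostic model over partial observations, a simulated physician-agent
    collaboration protocol, and evaluation statistics (macro AUROC and F1,
    general accuracy for compound diagnoses, inquiry/recall counts, normalized
    Kendall tau distance, and bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    pROC,
    nnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
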