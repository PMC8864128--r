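Package: framecast
Title: Categorical Dynamic Bayesian Networks for Tailoring Framed Health Messages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Elicits a three-slice categorical dynamic Bayesian network from
    two-wave randomized message-framing studies, reinterprets it as a graphical
    causal model to estimate average potential effects of gain, non-loss,
    non-gain and loss message framings on change in red/processed-meat
    intention, and profiles a fully enumerated simulated population by soft
    clustering to extract receiver prototypes. Includes a calibrated synthetic
    cohort generator, quantile discretization, exact inference on categorical
    networks, information-gain parent-set screening, Hand-Till multiclass AUC
    model selection with leave-one-out evaluation, back-door adjusted effect
    estimation, and t-SNE embedding of effect profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
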