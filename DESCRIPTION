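Package: numtwin
Title: Digital-Twin Modelling of Numerical Cognition with Gain-Modulated Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how neural excitability shapes arithmetic learning using
    gain-modulated, biologically inspired recurrent convolutional networks
    trained on visually presented addition and subtraction problems. Provides
    a procedural stimulus generator, a gain-sweep training protocol, behavioral
    metrics (accuracy, systematic error, imprecision, response entropy),
    representational similarity analysis, mean-field manifold geometry
    (capacity, dimensionality, center correlations), and a digital-twin
    matching procedure that pairs networks with a synthetic cohort of children
    via normalized achievement scores, including simulated extended-training
    remediation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
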