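Package: priorpop
Title: Learned Stimulus Priors in Neural Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how feedforward
    rate networks learn to represent stimulus prior probabilities from
    trial-by-trial error feedback.  Provides a Poisson tuning-curve encoder
    for one-dimensional stimuli, a trainable input-hidden-readout network
    with optional cue-driven gain and bias modulation, closed-form Bayesian
    ideal observers (posterior classification and MAP estimation) used as
    optimality references, and a suite of representation analyses: hidden
    population sparsity, activation-threshold (bias) comparisons, cue
    gain-versus-bias attribution and ablation, tuning-curve geometry (peak,
    maximal-slope location, full width at half maximum) and perceptual-bias
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
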