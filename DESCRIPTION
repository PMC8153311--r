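Package: costbayes
Title: Costly Bayesian Inference of a Bernoulli Probability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online inference of a Bernoulli probability regularized by a
    cognitive cost on the inferred posterior. Implements two observers: a
    precision-cost observer, whose posterior is a Beta distribution over
    exponentially filtered outcome counts and whose point estimate follows an
    AR(1) process, and an unpredictability-cost observer, whose posterior is
    an N-th power of a per-observation profile and whose estimate undergoes a
    pitchfork bifurcation at unit cost strength. Provides a direct variational
    minimizer over grid densities that validates both closed forms, simulators
    for belief-switching dynamics (flight durations, arcsine-law sojourn
    statistics of the underlying random walk), and a command-line interface
    for scripted experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
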