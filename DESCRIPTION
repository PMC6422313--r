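Package: latstep
Title: Stochastic Optimal Regulation of Lateral Stepping in Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Control-template models of step-to-step regulation of lateral
    stepping during walking. Implements stochastic optimal single-step
    regulators of lateral body position, heading, and step width (alone or
    as weighted multi-objective mixtures), discrete-map simulation of
    foot-placement sequences with optional lateral-boundary and step-width
    constraints, and the fluctuation-analysis battery used to compare
    regulation strategies against human stepping dynamics: time-series
    variability, detrended fluctuation analysis (DFA) scaling exponents,
    and direct step-to-step error-correction regression. Includes parameter
    sweep drivers, a mean +/- 1 SD reference-band comparison rule, and a
    synthetic reference-fixture generator emulating human treadmill trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
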