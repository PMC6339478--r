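Package: foramDynamics
Title: Population Dynamics of Larger Benthic Foraminifera from
    Size-Frequency Samples
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the 'natural laboratory' approach to estimating
    growth rates, reproduction timing and longevity of larger benthic
    foraminifera from repeated size-frequency samples. Monthly chamber-number
    and test-diameter frequency distributions are screened for normality,
    decomposed into normally distributed cohort components by nonlinear
    regression, linked into generations, and fitted with Michaelis-Menten
    (chamber building rate) and generalized Michaelis-Menten (diameter
    increase rate) growth curves including a grid search for the
    pre-observation onset interval. Fitted curves are inverted to
    per-specimen birthdates, from which monthly reproduction histograms,
    Lomb periodograms, Nyquist-bounded sinusoid scans, harmonic series and
    maximal longevity are derived. A forward population simulator with
    seasonal (nonhomogeneous Poisson) reproduction and individual growth
    variability provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
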