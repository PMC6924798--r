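Package: aacdce
Title: Discrete Choice Experiment Design and Mixed Logit Analysis for
    Vignette-Conditioned Preference Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing discrete choice
    experiments (DCEs) in which each choice task is conditioned on a
    hypothetical vignette, as in studies of how augmentative and alternative
    communication (AAC) professionals choose communication systems for
    children.  Provides attribute-scheme enumeration with exclusion rules,
    D-efficient blocked designs via coordinate exchange, simulation of panel
    choice data under a random-utility model with normally mixed coefficients
    whose means and standard deviations shift with vignette covariates,
    maximum simulated likelihood estimation of the interaction mixed logit
    with scrambled Halton draws, backward step-wise model selection by the
    Bayesian Information Criterion, Holm-adjusted inference, odds ratios, and
    relative interaction attribute importance (RIAI) summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
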