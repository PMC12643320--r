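Package: srtraces
Title: Trial-by-Trial Successor-Representation Learning from Reaction Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how people learn multi-step predictive
    representations (the successor representation, SR) from sequential
    experience, using reaction times in graph serial-reaction-time tasks.
    Provides 4-regular stimulus graphs and random-walk sequence generators;
    trial-by-trial predictive learners (recency, one-step transition,
    SR-TD(lambda) with dutch eligibility traces, static SR) together with
    closed-form SR oracles; a shifted log-normal reaction-time observation
    model; hierarchical expectation-maximization fitting with
    Laplace-approximated marginal likelihoods and AIC-penalized model
    comparison; model-agnostic sequence-pattern signature analyses of trace
    and bootstrap updating; and a synthetic-data generator for parameter- and
    model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    lme4,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
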