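Package: cequiv
Title: Confounding Equivalence in Causal Diagrams: Graphical Tests and
    Estimator Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying confounding equivalence (c-equivalence) of
    covariate adjustment sets in causal diagrams with a binary exposure and
    outcome.  Provides a causal directed-acyclic-graph class with
    d-separation, back-door (G-admissibility) and Markov-boundary tests and
    the necessary-and-sufficient c-equivalence verdict; a registry of four
    benchmark diagrams with binary logistic structural-equation models and a
    seeded Bernoulli data generator; an exact do-calculus oracle for the
    true average causal effect on the log odds-ratio scale together with the
    population limits of covariate-adjusted logistic regression and
    stabilized inverse-probability-weighted marginal structural models; the
    corresponding finite-sample estimators; and a replicate/sweep simulation
    engine that aggregates Monte-Carlo bias and precision against the exact
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
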