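Package: helor
Title: Probabilistic Research Statements, Hypothesis Elimination, and
    Active Compound Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recording research statements with evidence-linked,
    time-varying probabilities, in the style of the HELO (HypothEsis and Law
    Ontology) scheme.  Statements are logical expressions over ontology-style
    entities; each carries a trajectory of timestamped prior and posterior
    probability records with their estimation method (Bayesian inference,
    expert estimation, statistical calculation, deduction, abduction,
    induction, homological inference) and links to supporting, refuting and
    disputing evidence.  Two reasoning engines operate on these records:
    eliminative and Bayesian updating over mutually exclusive hypothesis sets
    with entropy-based experiment selection, and Gaussian-process active
    k-optimization of compound libraries with most-probable-improvement,
    maximum-expected-improvement, confidence-bound and random selection
    strategies.  Includes deterministic fixtures for three worked examples
    (yeast aromatic amino acid pathway eliminations, the sirtuin lifespan
    hypothesis timeline, and synthetic QSAR libraries) and a JSON
    knowledge-base serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
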