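Package: correctmem
Title: Simulation and Dual-Process Modeling of Memory for Corrected Fake News
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how fake-news corrections affect later memory
    and belief accuracy in the three-phase news-headline paradigm. Provides a
    counterbalanced list-design generator with presentation-order constraints,
    a calibrated generative simulator of trial-level recall, correction
    classification, fake-news recall and belief-rating data, response-category
    coding, mixed-effects analyses of recall/intrusion/fake-recall
    probabilities and belief ratings with crossed participant and item random
    intercepts, and a hierarchical Bayesian multinomial processing tree (MPT)
    separating recollection- and familiarity-based retrieval, with
    credible-interval contrasts and parameter-recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    car,
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
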