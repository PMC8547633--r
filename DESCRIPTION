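Package: herdsync
Title: Synchronization Models for Multilevel Animal Societies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study behavioural synchronization in multilevel
    animal societies such as feral horse herds. Builds proximity-based
    association networks from positional scan data (bimodal distance
    histogram, nadir threshold, chain connectivity, simple ratio index),
    scores dyadic synchronization rates and collective state-change
    phases, estimates mimetic-model parameters by exponential survival
    fits, simulates seven candidate synchronization hypotheses
    (independent, anonymous, unit-level and herd-level social mimetism,
    each in absolute and proportional form) with refractory-period state
    dynamics, and ranks the hypotheses against observed or synthetic
    data with Kolmogorov-Smirnov and Mantel tests. A synthetic-society
    generator reproduces the statistical structure of drone-based scan
    observations so the full pipeline can be exercised without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    KernSmooth,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
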