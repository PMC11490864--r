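Package: ineqmed
Title: Interventional-Effects Causal Mediation Analysis of Health Inequities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how much of the inequity in binary health outcomes
    between an exposed and an unexposed group of children would be removed by a
    hypothetical intervention eliminating a binary mediator such as
    interpersonal racial discrimination, using interventional-effects causal
    mediation estimated by extended g-computation with an exposure-induced
    intermediate confounder. Includes a clustered synthetic-cohort generator
    with a brute-force oracle for the true interventional effects, multiple
    imputation by chained equations with Rubin's-rules pooling, log-Poisson
    generalized estimating equations for risk ratios with exchangeable working
    correlation, clustered bootstrap standard errors, and an end-to-end
    pipeline emitting descriptive, association and mediation report tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
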