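Package: traitpanel
Title: County-Level Text-Derived Personality and Interval-Censored Mortality Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking Big Five personality scores mined
    from geo-tagged short texts to interval-censored county mortality counts.
    Provides lexicon-based trait scoring with percentile ranking, superordinate
    personality components (KMO, Cronbach alpha, eigenvalue-based PCA
    retention), maximum-likelihood random-effects interval regression by
    Gauss-Hermite quadrature with cluster bootstrap standard errors, a
    control-function endogeneity correction with instrument diagnostics
    (Anderson, Cragg-Donald, Sargan, Davidson-MacKinnon), and a synthetic-data
    generator that emulates small-cell suppressed mortality surveillance so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    sandwich
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
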