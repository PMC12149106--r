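Package: pmcindex
Title: Policy Modeling Consistency (PMC) Index Evaluation of Policy Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative evaluation of policy document corpora with the
    Policy Modeling Consistency (PMC) index model: binary sub-variable
    coding of policy texts against a two-level evaluation framework,
    first-level variable scoring, PMC index computation with
    report-parity or full-precision rounding, four-grade classification,
    corpus-level aggregates, 3x3 PMC-surface construction and rendering,
    and supporting text mining (tokenisation, high-frequency terms,
    co-occurrence semantic networks). Ships the published evaluation
    framework for Chinese traditional-medicine drug registration policies
    together with its complete first-level score table, and includes
    seeded generators for synthetic coding matrices and token corpora so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
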