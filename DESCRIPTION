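Package: sppa
Title: Signaling Pathway Perturbation Analysis from Ranked Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the perturbation of every pathway in a gene-set collection
    from a ranked differential-expression gene list using a weighted
    running-sum statistic, assesses significance by gene-set or sample-label
    permutation, normalizes effect scores against the permutation null,
    weights them by pathway size, and aggregates them into per-category
    normalized effect scores and a single total effect score (TES) that
    summarizes the overall transcriptomic impact of an exposure. Includes a
    synthetic-data generator (pathway hierarchies, differential statistics,
    negative-binomial count matrices with planted perturbations) and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
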