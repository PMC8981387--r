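Package: metsig
Title: Differential Metabolites and Pathway Signatures from Untargeted
    Metabolomics Peak Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for untargeted metabolomics peak-area data
    from multi-tissue two-group designs. Implements batch median scaling,
    minimum-value imputation and log transformation; per-metabolite
    two-group linear-model testing with fold-change based differential
    metabolite (DM) calling; cross-tissue detection and DM overlap
    summaries; pathway signature scoring by a direction z statistic and an
    enrichment value on named-metabolite backgrounds; metabolite set
    enrichment analysis (MSEA) with a permutation null; and
    metabolite-metabolite interaction subnetworks with betweenness-ranked
    hubs. Ships a synthetic-data generator with planted ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
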