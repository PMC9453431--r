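Package: phenanchor
Title: Concentration-Response Transcriptomics with Phenotypic Anchoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for concentration-response transcriptomics in developmental
    toxicology: negative-binomial differential expression across a dilution
    series, Williams-trend-gated benchmark concentration (BMC) modeling of
    genes and gene sets with ten continuous model families, tree-ensemble
    co-expression network inference with greedy modularity module detection,
    a leave-one-concentration-out (LOCO) edge-weight perturbation analysis,
    binomial log-logistic modeling of teratogenicity incidence, and
    phenotypic anchoring of transcriptomic BMCs to an apical dose-response.
    Includes a seeded synthetic-data generator that emulates an 8-point
    geometric exposure series with replicate pools, planted co-expressed
    gene modules and binary developmental outcomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    igraph,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
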