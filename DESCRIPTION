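Package: faresponse
Title: Genetic and Epigenetic Analysis of Folic-Acid Response in
    Hyperhomocysteinemia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired pre/post folic-acid
    supplementation cohorts of hyperhomocysteinemia patients: responder
    stratification from homocysteine change, normality-gated paired
    statistics, LINE-1 bisulfite-pyrosequencing methylation
    summarization, a whitelist-filtered multi-tissue epigenetic clock
    (elastic-net retraining on the Horvath age transform), per-group
    variant carrier frequencies with dual-threshold hotspot calls and a
    pathway-gene-mutation bipartite graph, and per-gene mutation-burden
    versus biological-age-change association. Includes a seeded
    synthetic-cohort generator that emulates every input the pipeline
    consumes, so the full analysis is reproducible without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
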