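Package: scrrb
Title: SC-RRB Balance Subtyping and Replicable Functional Connectome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stratifies autistic individuals by the balance between
    social-communication (SC) and restricted repetitive behavior (RRB)
    symptom severity derived from ADI-R item-level data, and links the
    resulting subtypes to resting-state functional connectivity and
    transcriptomic annotation. Provides DSM-5 percentage severity scoring
    of ADI-R items, z-normalized difference-score subtyping with
    out-of-sample prediction, ridge-regularized partial-correlation
    network estimation, edge-wise mixed models with replication Bayes
    factors and consensus-edge detection across subtype thresholds,
    spatial gene-expression decoding across donor brains, hypergeometric
    gene-set enrichment, seeded synthetic-data generators for every
    stage, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
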