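Package: ieaclust
Title: Independent Enrichment Analysis of Gene Lists via Annotation Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters a gene list into subgroups using binary Gene Ontology or
    transcription-factor target annotation matrices by non-negative matrix
    factorization, selects the number of clusters with AIC and a
    dimension-filtered dAIC score, and cross-evaluates each cluster by
    enrichment of the other annotation system (one-sided Fisher's exact test
    with Benjamini-Hochberg FDR control). Builds non-nested cluster trees with
    correlation-weighted edges between adjacent levels, computes
    inter-correlation between trees from different annotation systems, and
    ships a synthetic generator of coupled binary annotation systems with a
    planted partition for power and error-control studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
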