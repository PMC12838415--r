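Package: bloodmet
Title: Enrichment, Tissue-Relevance and Network Analysis for Blood Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical toolkit for curated human blood metabolite resources:
    over-representation analysis (Fisher's exact or binomial test with
    multiple-testing correction) against metabolite term sets, pre-ranked
    metabolite set enrichment analysis (weighted running-sum statistic with
    permutation nulls, normalized scores and FDR), tissue-relevance inference
    for metabolites from associated-protein expression across tissues,
    bipartite metabolite-protein network analysis (centralities, centrality
    levels, Jaccard similarity, community detection, hub selection),
    Cohen's-kappa based reduction of redundant enrichment terms, and seeded
    synthetic-data generators with planted ground truth for power and
    calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
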