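# bloodmet

Enrichment, tissue-relevance and network analysis for curated human blood
metabolite resources.

Blood metabolomics studies routinely end with a list of interesting
metabolites, or a ranked profile of per-metabolite effect sizes, and three
recurring questions: *which biological annotations are over-represented in
this list?* — *which tissues are these metabolites relevant to?* — *how do
they sit inside the metabolite–protein association network?* `bloodmet`
implements the statistical layer that answers them against a curated catalog
of blood metabolites with multi-namespace identifiers, annotation term sets
(Class / Pathway / Disease / Drug), tiered metabolite–protein associations
and protein tissue-expression data:

* **ORA** — over-representation analysis: one-sided Fisher's exact
  (hypergeometric upper tail, `phyper`) or binomial test per term, with
  Benjamini–Hochberg or Bonferroni correction.
* **MSEA** — pre-ranked metabolite set enrichment: the weighted running-sum
  enrichment score `ES ∈ [-1, 1]` (hit increments `|s|^p / Σ|s|^p`, miss
  decrements `1/(N − N_hit)`), metabolite-label permutation nulls,
  `NES = ES / mean(|null ES| same sign)`, smoothed nominal p-values and
  GSEA-style FDR q-values.
* **TSA** — tissue relevance of a metabolite from its associated proteins'
  expression: three criteria per tissue (Fisher over-representation of
  tissue-elevated partners; partner count above mean + 1.96 × SD across
  tissues; paired one-sided Wilcoxon of tissue nTPM against each protein's
  other-tissue median), a ≥3-elevated-partner eligibility filter,
  Tissue Relevant / Low tissue relevance / Unknown categories and
  High/Medium/Low reliability; plus tissue enrichment of query lists.
* **MPNet** — bipartite metabolite–protein network analysis: degree,
  closeness, betweenness; High/Medium/Low centrality levels from log2-degree
  median + MAD; Jaccard similarity; Louvain (resolution 1.5, seeded) or
  deterministic greedy community detection; hub selection and a 100-edge
  display subgraph.
* **Term reduction** — Cohen's kappa between term membership vectors over
  the background, greedy selection of representatives so that no pair
  exceeds κ = 0.3, and cluster assignment of the remaining terms.
* **Evidence tiers** — associations classified as inferred (1), curated (2)
  or validated (3 = multi-source or independently validated).
* **Synthetic data** — seeded generators for all five input kinds with
  planted ground truth (enriched terms, hub proteins, tissue-relevant
  metabolites) for calibration and power studies.

See `vignettes/bloodmet-methods.Rmd` for the statistical details and design
choices.

## Worked example

Simulate a small resource with one planted 18-member term whose members'
scores are shifted by δ = 2, then run ORA on the top of the ranked list and
MSEA on the full profile:

```r
library(bloodmet)

cfg <- synth_config(seed = 42, n_metabolites = 300, n_terms = 12,
                    planted_terms = list(list(term_id = "bile-acids",
                                              size = 18, delta = 2)))
gen  <- generate_ranked_scores(cfg)
coll <- build_term_collection(gen$terms, gen$catalog$hub_id)

summarize_catalog(gen$catalog)
#> Catalog summary: 300 metabolites
#>   Lipid                       170  (56.67%)
#>   Xenobiotics                  60  (20.00%)
#>   Amino acid                   28  (9.33%)
#>   ...

run_ora(gen$ranked$hub_id[1:40], coll, method = "fisher", adjust = "BH")
#>      term_id n_overlap n_term expected fold_enrichment    p_raw p_adjusted
#> 1 bile-acids        15     18     2.40            6.25 3.30e-12   3.96e-11
#> 2      T0011         9     35     4.67            1.93 2.74e-02   1.65e-01
#> 3      T0003         4     13     1.73            2.31 7.93e-02   3.17e-01

run_msea(gen$ranked, coll, msea_config(n_permutations = 1000, seed = 7))
#>      term_id size     ES   NES p_nominal   FDR
#> 1 bile-acids   18  0.865  2.48   0.00152 0.000
#> 2      T0005   40 -0.341 -1.36   0.05575 0.193
#> 3      T0004    6 -0.645 -1.49   0.08617 0.287
```

Reading the output: 15 of the 40 top-ranked metabolites fall in the planted
term against an expectation of 2.4 (6.25-fold enrichment, BH-adjusted
p ≈ 4e-11), and the same term tops the MSEA ranking with ES 0.87 and
NES 2.48 at FDR ≈ 0 — the planted signal is recovered by both routes, while
the unplanted terms stay near the null.

The same analyses are available from the shell via the installed
`inst/scripts/bloodmet` entry point (`ora`, `msea`, `tsa call`,
`tsa enrich`, `mpnet`, `reduce`, `simulate`); every run writes a JSON
manifest with parameters, input checksums and seeds.

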