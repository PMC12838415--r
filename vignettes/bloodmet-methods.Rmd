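---
title: "Statistical methods behind bloodmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind bloodmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodmet)
options(bloodmet.log_level = "quiet")
```

`bloodmet` packages the analytical layer that sits on top of a curated human
blood metabolite resource: enrichment testing of metabolite lists and ranked
profiles against annotation term sets, inference of the tissues a blood
metabolite is relevant to, analysis of the bipartite metabolite–protein
association network, and reduction of redundant enrichment terms. This
vignette explains each method, its assumptions, the tunable parameters, and
the design choices made where the underlying procedure was open to
interpretation. It also describes what the synthetic-data generators emulate
and, as importantly, what they do not.

## The data model

A **catalog** holds one row per curated blood metabolite: an opaque unique
key, a display name, pipe-delimited synonyms, a category from a closed
nine-value set (Lipid, Xenobiotics, Amino acid, Peptide, Carbohydrate,
Nucleotide, Cofactors and vitamins, Energy, Others), and up to sixteen
structured registry identifiers (HMDB, KEGG, BioCyc, PubChem, PDB, ChEBI,
DrugBank, Phenol-Explorer, FooDB, KNApSAcK, Chemspider, VMH, LipidMaps,
SwissLipids, SMILES, InChI Key); together with names/synonyms these form the
17 supported identifier namespaces. Names and synonyms are matched
case-insensitively because capitalization of common names is unstable across
sources; registry identifiers are matched case-sensitively because registries
fix their own casing. Ambiguous synonym hits are returned in full (sorted by
key) rather than silently resolved — the curation process gives no
disambiguation rule, so the caller must decide.

**Annotation terms** (Class, Pathway, Disease, Drug) are sets of metabolite
keys. A term collection intersects every term with a background universe
first and then drops terms with fewer than `min_size = 5` members; five is
the conventional floor below which an enrichment test is uninformative.

**Associations** connect a metabolite to a protein with provenance from one
or more of three source types — `curated` (manually curated databases),
`modeling` (genome-scale metabolic models) and `correlation`
(population-scale omics correlation). Duplicate rows for the same pair are
merged (sources unioned, validation flags OR-ed) and each unique pair gets an
evidence tier:

* **Tier 3 (validated)** — at least two source types, or independent
  validation (an independent cohort, or an external chemical–protein
  interaction database). Independent validation alone is sufficient: we read
  "supported by at least two approaches *or* validated independently" as two
  separate sufficient conditions.
* **Tier 2 (curated)** — a single curated source.
* **Tier 1 (inferred)** — modeling and/or correlation only.

Tier assignment is monotone in evidence (adding a source or a validation flag
never lowers the tier) and partitions any association set; both properties
are asserted in the test suite.

## Over-representation analysis (ORA)

For an input list of metabolites, each term is tested for over-representation
with a one-sided upper-tail test. With background size $N$, term size $K$,
(mapped, deduplicated) input size $n$ and overlap $k$:

* **Fisher / hypergeometric**: $p = P(X \ge k)$, $X \sim
  \mathrm{Hypergeom}(N, K, n)$, computed with `phyper`. This equals a
  one-sided Fisher's exact test on the 2×2 table, which the test suite
  verifies against `fisher.test` and against exhaustive enumeration of draws
  on small backgrounds.
* **Binomial**: $p = P(X \ge k)$, $X \sim \mathrm{Binomial}(n, K/N)$ — the
  with-replacement approximation. Note $k$ may exceed $K$ under this model,
  so the binomial path validates only $k \le n \le N$.

Only the over-representation direction is offered; asking whether a term is
*depleted* in an input list is a different scientific question and not part
of this toolkit. Raw p-values are corrected across terms with
Benjamini–Hochberg (default) or Bonferroni via `p.adjust`. When a user
supplies a custom background it is intersected with the collection universe
and term memberships are re-intersected with the result — the conservative
reading of "background adjustment". Input identifiers that do not map to the
background are counted and logged; an input that maps to nothing is an
error that names the unmapped identifiers.

**Calibration and discreteness.** A one-sided hypergeometric test is
discrete: its exact size at a 0.05 threshold is the largest achievable
p-value below 0.05 and depends on $(N, K, n)$. For small terms the test is
markedly conservative. The calibration study in the test suite therefore
uses problem sizes (background 2000, input 400, term sizes 29–104) at which
the exact size — computed analytically from the hypergeometric tail before
any simulation — lies in $[0.046, 0.05]$, so a Monte-Carlo rejection-rate
estimate is meaningfully comparable to the nominal level. At smaller sizes
the same code is correct but conservative, which users should expect in
practice.

## Metabolite set enrichment analysis (MSEA)

MSEA takes a two-column ranked list (metabolite, score), sorts it by score
descending (ties broken by key for determinism), and computes for each term
the classic weighted running-sum statistic: walking the list, the sum rises
by $|s_i|^p / \sum_{hits} |s|^p$ at each member and falls by $1/(N -
N_{hit})$ at each non-member; the **enrichment score (ES)** is the signed
maximum deviation, always in $[-1, 1]$, and the **leading edge** is the set
of members at or before (positive ES) or at or after (negative ES) the
extremum. The weight exponent defaults to $p = 1$ (scores weight the
statistic); $p = 0$ gives the unweighted Kolmogorov–Smirnov-like variant.
If every member score is exactly zero the hit increments fall back to
$1/N_{hit}$ rather than dividing by zero. When the running sum's maximum and
minimum tie exactly in magnitude the first extremum along the list wins;
this tie-break is the only place where the sign of ES is conventional.

The null distribution is obtained by **metabolite-label permutation**:
random member sets of the same size drawn uniformly from the ranked
universe. Phenotype permutation is impossible here because the input
contract is a pre-ranked list; this is the standard trade-off for pre-ranked
enrichment and means the null reflects random gene-set membership, not
between-sample variability. One null of `n_permutations` draws (default
1000) is computed per distinct set size and shared by all terms of that
size; each size's null is seeded independently of term order, so results for
one term never change when another term is added.

From the null: the **nominal p-value** is the smoothed same-sign tail
fraction $(r + 1)/(m + 1)$, where $r$ counts same-sign null scores at least
as extreme and $m$ is the number of same-sign null scores — never exactly 0
and never above 1; the **normalized enrichment score** is $\mathrm{NES} =
ES / \operatorname{mean}(|ES_{null}|\ \text{of the same sign})$ (undefined,
with a warning, if no null score shares the sign); and the **FDR q-value**
compares tail fractions of the pooled normalized null with the observed NES
distribution, per sign, clipped to $[0, 1]$ — the canonical GSEA
formulation. Results are sorted by FDR, then $|\mathrm{NES}|$. Given the
same seed, inputs and configuration, results are bit-identical.

## Tissue relevance analysis (TSA)

The idea: a blood metabolite is relevant to a tissue when the proteins it
associates with are preferentially expressed there. Inputs are the
metabolite's associated proteins and a protein × tissue table of nTPM values
with per-cell elevation labels (`tissue enriched`, `tissue enhanced`,
`group enriched` — collectively "tissue elevated" — or `none`); a protein is
"detected" in a tissue when nTPM exceeds 1. Three complementary criteria are
evaluated per tissue:

1. **Over-representation** — one-sided Fisher's exact test of the overlap
   between the metabolite's proteins and the tissue-elevated proteins over
   the protein universe; flagged at p < 0.05.
2. **Count outlier** — the per-tissue counts of associated tissue-elevated
   proteins form a sample; a tissue is flagged when its count strictly
   exceeds mean + 1.96 × sample SD. The envelope variant (sample SD vs
   population SD vs a percentile interval) is an open choice; the
   normal-theory sample-SD envelope is the most direct reading and is
   isolated in one function (`criterion2_count_outlier`) for substitution.
   With equal counts the SD is zero and nothing is flagged (strict
   inequality).
3. **Expression elevation** — among associated proteins detected in the
   tissue, a paired one-sided Wilcoxon signed-rank test of each protein's
   nTPM in the tissue against that protein's median across all other
   tissues; flagged at p < 0.05. Pairing respects per-protein expression
   baselines. Zero differences are dropped (standard signed-rank practice);
   the exact distribution is used up to 25 non-zero pairs, the normal
   approximation above. Fewer than two detected proteins gives a missing
   p-value and no flag.

A (metabolite, tissue) pair is **eligible** only when at least three of the
metabolite's proteins are tissue-elevated there; ineligible pairs are never
evaluated, which suppresses spurious calls from tiny protein sets and is
asserted as an invariant ("ineligibility dominates"). Eligible pairs where
at least one criterion holds are **Tissue Relevant**; eligible pairs
failing all three are **Low tissue relevance**; ineligible pairs (including
metabolites with no associations) are **Unknown**. Relevance reliability:
**High** = all three criteria; **Medium** = two criteria, or one plus
curated localization support for that tissue; **Low** = one unsupported
criterion. Criterion p-values are used at the raw 0.05 threshold with no
cross-tissue correction — faithful to the procedure this package
reimplements, though not statistically ideal; users comparing many tissues
should keep that in mind. The tissue count is whatever the expression table
provides; nothing is hard-coded to the 36 tissues of the usual atlas.

Tissue *enrichment* of a query list reuses the ORA engine with tissues as
terms, over the High/Medium-reliability tissue → metabolite sets.

## Metabolite–protein network analysis

The association network is unweighted, undirected and strictly bipartite
(metabolite–protein edges only), built from tier-filtered associations with
optional node filters (igraph underneath). Centralities: degree; classic
closeness normalized by component size − 1, computed within connected
components so values stay in $[0, 1]$; unnormalized shortest-path
betweenness. **Centrality levels** follow a robust log-scale rule: with
$s = \log_2(\mathrm{degree})$, a node is High when $s >$ median + 2 × MAD,
Medium above median + 1 × MAD, else Low, where MAD is the *unscaled* median
absolute deviation (no 1.4826 consistency factor). The rule is
scale-equivariant: doubling all degrees shifts every $s$ by one and changes
nothing. Degrees are at least 1 by construction (isolated nodes are dropped
at build time), so no +1 offset is needed inside the logarithm.

Jaccard similarity between two same-side nodes is
$|N(a) \cap N(b)| / |N(a) \cup N(b)|$, defined as 0 when both neighborhoods
are empty; cross-side comparison is an error because the two sides'
neighborhoods live in different node spaces.

**Communities** come from Louvain modularity optimization at resolution 1.5
(the analysis setting of the upstream study; seeded, reproducible) or from
deterministic greedy modularity optimization (`cluster_fast_greedy`), which
has no resolution parameter — the `resolution` argument applies to Louvain
only. On small test graphs both methods reach at least 95% of the
exhaustive-search modularity optimum.

**Hubs** are nodes in the top 5 by degree *and* top 5 by closeness. Tie
handling is subtle: a tie group is admitted only when the whole group fits
within the top 5 (max-rank ≤ 5). This makes the center of a star its unique
hub (the leaves tie *en masse* and are excluded as a group) while a fully
symmetric graph — where even the leading tie group exceeds five — returns
the whole tie group flagged as degenerate. The default display selection is
the top 10 proteins by degree (closeness breaking ties) and, given query
metabolites, the 5 metabolites with the highest maximum Jaccard similarity
to any query. The **display subgraph** caps the edge count (default 100) by
adding edges greedily in order of (larger endpoint degree, smaller endpoint
degree, lexicographic name), so hub-incident edges enter first.

## Non-redundant term reduction

Enriched terms often overlap heavily. Pairwise similarity is Cohen's kappa
between the two terms' binary membership indicators over the **enrichment
background** (not the union of the two terms): agreement must be measured on
a common frame, and the background is the only frame the pipeline
guarantees. With observed agreement $O$ and chance agreement
$E = p_A p_B + (1 - p_A)(1 - p_B)$, $\kappa = (O - E)/(1 - E)$; the
degenerate case $E = 1$ (both terms empty, or both the whole universe) is
perfect agreement and returns 1 by convention. Terms are ranked by adjusted
significance (ties by term id) and representatives are selected greedily
from the top: a term is accepted iff its kappa with every previously
accepted representative is ≤ 0.3 (strictly greater than 0.3 means
redundant, on both sides of the algorithm). Every non-representative then
joins the best-ranked representative with kappa > 0.3; a term linked to no
representative — possible only when the caller ranks a significance-filtered
subset — becomes a logged singleton. The output invariant (no representative
pair with kappa > 0.3) is asserted on every run.

## Synthetic data: what it emulates and what it does not

The generator family (`synth_config` plus `generate_catalog`,
`generate_associations`, `generate_expression`, `generate_ranked_scores`)
produces every input the analysis modules consume, with planted ground truth
for power and calibration studies. Every generator is a pure function of its
configuration: one master seed is expanded into fixed per-generator
substreams, so regenerating one input never perturbs another.

Defaults are chosen to make small fixtures look like the real resource at
scale: category proportions follow the curated blood metabolome (58.7%
lipids down to 0.5% energy metabolites); association sources mix at the
observed contribution of correlation, curated and modeling evidence; the
nTPM baseline is lognormal (meanlog 2, sdlog 1 — median ≈ 7 nTPM, a
realistic transcript scale); each (protein, tissue) cell is independently
background-elevated at rate 0.03 with a fold-4 expression bump, which makes
roughly two thirds of proteins elevated somewhere across 36 tissues,
matching the share of tissue-elevated proteins in real association networks.
Planted structure: terms of controlled size whose members' scores are
shifted by δ (for MSEA power studies), hub proteins forced to ten times the
median protein degree (for centrality-level recovery), and
(metabolite, tissue, fold) plants whose associated proteins are elevated and
fold-times over-expressed in the target tissue (for TSA recovery).

What the generators do **not** emulate: correlated metabolite scores (real
fold-change profiles are strongly correlated within pathways, which widens
enrichment nulls), hub-skewed degree distributions outside the explicit
plants, curation noise and synonym collisions beyond simple duplication,
inter-tissue expression correlation, or compositional effects in the
association sources. Passing the recovery and calibration suites therefore
demonstrates algorithmic correctness under clean planted signal, not
field performance on real cohort data.

One property of planted tissue relevance deserves emphasis: plants operate
on *proteins*, and proteins are shared. A non-planted metabolite that
happens to associate with three or more of a planted metabolite's
over-expressed partners is *genuinely* tissue relevant by the criteria —
that is leakage of ground truth labels, not a false call. The recovery
study in the test suite therefore uses a sparse design (2 planted
metabolites among 60, 1000 proteins, association density 0.015) in which
such label contamination is rare, so that the planted/non-planted split
remains a meaningful truth standard.

## Numerical and interface conventions

Percentages are rounded half-up (two decimals for category shares, one for
source shares) to match conventional reporting; base `round()`'s banker's
rounding is deliberately avoided for printed shares. All tabular I/O is
strict TSV (header, UTF-8, "." decimal, no quoting); readers reject
malformed rows with line numbers. The command line (`bm_cli()`, or the
installed `bloodmet` script) exposes `ora`, `msea`, `tsa call`/`tsa enrich`,
`mpnet`, `reduce` and `simulate`, writes one JSON run manifest (parameters,
input checksums, seed, version, timestamp) next to every output, and exits 0
on success, 1 on data errors, 2 on usage errors. All randomness flows
through explicit `--seed` flags.

## Known limitations

* TSA criterion thresholds are uncorrected across tissues (by design, see
  above); the criterion-2 envelope assumes approximate normality of
  per-tissue counts, which is rough for very sparse metabolites.
* The discrete ORA tests are conservative for small terms and small inputs.
* NES is undefined for a term whose same-sign permutation null is empty
  (reported missing with a warning); extremely small permutation counts make
  this more likely.
* Kappa over the full background makes two small terms in a large universe
  look dissimilar even when one contains the other; if term-local agreement
  is wanted, compute kappa over a restricted universe and pass it to
  `select_representatives` directly.
* The Louvain implementation depends on igraph's RNG; partitions are
  reproducible under a fixed seed and igraph version but may differ across
  igraph versions.
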