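# Helper: merged association table for a fixed edge list.
assoc_from_edges <- function(met, prot, source = "curated") {
  merge_association_rows(data.frame(metabolite = met, protein = prot,
                                    source = source, stringsAsFactors = FALSE))
}

test_that("network construction is bipartite, tier-filtered and filterable", {
  rows <- data.frame(
    metabolite = c("M1", "M1", "M1", "M2", "M2"),
    protein = c("P1", "P2", "P3", "P3", "P4"),
    source = c("curated", "curated", "correlation", "modeling", "curated"),
    validated_independent = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  assocs <- merge_association_rows(rows)

  net <- build_network(assocs)
  expect_equal(igraph::ecount(net), 5L)
  expect_true(igraph::bipartite_mapping(net)$res)

  # star induced by one metabolite: 4 nodes, 3 edges
  star <- build_network(assocs, metabolites = "M1")
  expect_equal(igraph::vcount(star), 4L)
  expect_equal(igraph::ecount(star), 3L)

  # tier filter that removes everything is an error
  expect_equal(igraph::ecount(build_network(assocs, min_tier = 3)), 1L)
  rows1 <- rows[3, ]
  expect_error(build_network(merge_association_rows(rows1), min_tier = 3),
               "empty")
})

test_that("centralities take their closed forms on a star", {
  k <- 7
  assocs <- assoc_from_edges(rep("HUBM", k), sprintf("P%d", 1:k))
  net <- build_network(assocs)
  rec <- centrality(net)
  center <- rec[rec$node == "HUBM", ]
  expect_equal(center$degree, k)
  expect_equal(center$closeness, 1)
  expect_equal(center$betweenness, choose(k, 2))
  leaf <- rec[rec$node == "P1", ]
  expect_identical(leaf$degree, 1L)
  expect_equal(leaf$betweenness, 0)

  # two disjoint edges: closeness 1 within each component
  two <- build_network(assoc_from_edges(c("Ma", "Mb"), c("Pa", "Pb")))
  expect_true(all(centrality(two)$closeness == 1))
})

test_that("centrality levels follow the median + MAD rule on log2 degrees", {
  lv <- centrality_levels(c(2, 4, 8, 8, 64))
  expect_identical(lv, c("Low", "Low", "Low", "Low", "High"))
  expect_identical(centrality_levels(rep(6, 10)), rep("Low", 10))
  expect_identical(centrality_levels(5), "Low")
  expect_error(centrality_levels(integer(0)), "empty")
  expect_error(centrality_levels(c(1, 0)), ">= 1")

  # scale equivariance: doubling all degrees shifts log2 scores by +1 and
  # leaves the level assignment unchanged
  set.seed(3)
  for (i in 1:10) {
    deg <- sample(1:200, 25, replace = TRUE)
    expect_identical(centrality_levels(deg), centrality_levels(2 * deg))
  }
})

test_that("Jaccard similarity is computed over shared neighborhoods", {
  assocs <- assoc_from_edges(c("M1", "M1", "M2", "M2", "M3"),
                             c("P1", "P2", "P2", "P3", "P4"))
  net <- build_network(assocs)
  expect_equal(jaccard_similarity(net, "M1", "M2"), 1 / 3)
  expect_equal(jaccard_similarity(net, "M1", "M3"), 0)
  expect_equal(jaccard_similarity(net, "M1", "M1"), 1)
  expect_error(jaccard_similarity(net, "M1", "P1"), "partition")
})

test_that("community detection recovers separated bipartite blocks", {
  # two disjoint complete bipartite K(3,3) blocks
  blocks <- rbind(
    expand.grid(metabolite = c("Ma1", "Ma2", "Ma3"),
                protein = c("Pa1", "Pa2", "Pa3")),
    expand.grid(metabolite = c("Mb1", "Mb2", "Mb3"),
                protein = c("Pb1", "Pb2", "Pb3")))
  assocs <- assoc_from_edges(as.character(blocks$metabolite),
                             as.character(blocks$protein))
  net <- build_network(assocs)
  for (method in c("louvain", "greedy")) {
    part <- detect_communities(net, method, seed = 1)
    expect_length(part$assignment, 12L)
    blocks_a <- unique(part$assignment[startsWith(names(part$assignment), "Ma") |
                                         startsWith(names(part$assignment), "Pa")])
    blocks_b <- unique(part$assignment[startsWith(names(part$assignment), "Mb") |
                                         startsWith(names(part$assignment), "Pb")])
    expect_length(blocks_a, 1L)
    expect_length(blocks_b, 1L)
    expect_false(blocks_a == blocks_b)
  }
  # determinism under a fixed seed
  p1 <- detect_communities(net, "louvain", seed = 42)
  p2 <- detect_communities(net, "louvain", seed = 42)
  expect_identical(p1$assignment, p2$assignment)
  expect_error(detect_communities(net, "spectral"), "arg")
})

test_that("detected modularity approaches the exhaustive optimum on a toy graph", {
  # two K(2,3) blocks joined by one bridge edge: 10 nodes
  blocks <- rbind(
    expand.grid(metabolite = c("Ma1", "Ma2"), protein = c("Pa1", "Pa2", "Pa3")),
    expand.grid(metabolite = c("Mb1", "Mb2"), protein = c("Pb1", "Pb2", "Pb3")),
    data.frame(metabolite = "Ma1", protein = "Pb1"))
  assocs <- assoc_from_edges(as.character(blocks$metabolite),
                             as.character(blocks$protein))
  net <- build_network(assocs)
  n <- igraph::vcount(net)

  # brute force over all partitions into <= 3 blocks (first node fixed)
  best <- -Inf
  grid <- expand.grid(rep(list(1:3), n - 1))
  for (r in seq_len(nrow(grid))) {
    mem <- c(1L, unlist(grid[r, ], use.names = FALSE))
    q <- igraph::modularity(net, mem)
    if (q > best) best <- q
  }
  for (method in c("greedy", "louvain")) {
    part <- detect_communities(net, method, resolution = 1, seed = 0)
    expect_gte(part$modularity, 0.95 * best)
    # beats the all-singletons partition
    singletons <- igraph::modularity(net, seq_len(n))
    expect_gte(part$modularity, singletons)
  }
})

test_that("hub selection intersects the degree and closeness top-5 lists", {
  k <- 8
  assocs <- assoc_from_edges(rep("HUBM", k), sprintf("P%d", 1:k))
  net <- build_network(assocs)
  rec <- centrality(net)
  rep <- select_hubs(net, rec)
  # the center dominates both rankings; leaves tie at closeness but miss
  # the degree top-5 cut only if ties keep them -- the center is always in
  expect_true("HUBM" %in% rep$hubs)
  expect_lte(length(rep$display_proteins), 10L)

  # fewer than 5 nodes: everything is in both top-5 lists
  small <- build_network(assoc_from_edges("M1", "P1"))
  rec_small <- centrality(small)
  expect_setequal(select_hubs(small, rec_small)$hubs, c("M1", "P1"))

  # display metabolites ranked by Jaccard similarity to the query
  assocs2 <- assoc_from_edges(c("Q", "Q", "M1", "M1", "M2"),
                              c("P1", "P2", "P1", "P2", "P3"))
  net2 <- build_network(assocs2)
  rep2 <- select_hubs(net2, centrality(net2), query_metabolites = "Q")
  expect_identical(rep2$display_metabolites[1], "M1")
})

test_that("the display subgraph caps edges with hub-first priority", {
  # star with 150 leaves: keep the 100 lexicographically-first leaf edges
  assocs <- assoc_from_edges(rep("HUBM", 150), sprintf("P%03d", 1:150))
  net <- build_network(assocs)
  rec <- centrality(net)
  sub <- display_subgraph(net, rec, max_edges = 100)
  expect_equal(igraph::ecount(sub), 100L)
  kept <- sort(substring(setdiff(igraph::V(sub)$name, "m:HUBM"), 3))
  expect_identical(kept, sprintf("P%03d", 1:100))
  expect_true(igraph::bipartite_mapping(sub)$res)

  # at or below the cap: identity
  small <- build_network(assoc_from_edges(c("M1", "M2"), c("P1", "P1")))
  expect_equal(igraph::ecount(display_subgraph(small, centrality(small))),
                   2L)
  # zero cap: empty graph
  empty <- display_subgraph(net, rec, max_edges = 0)
  expect_equal(igraph::ecount(empty), 0L)
})

test_that("network node/edge tables are written with communities attached", {
  assocs <- assoc_from_edges(c("M1", "M1", "M2"), c("P1", "P2", "P2"))
  net <- build_network(assocs)
  rec <- centrality(net)
  comm <- detect_communities(net, "greedy")
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(net, rec, comm, prefix)
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"))
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"))
  expect_identical(nrow(nodes), 4L)
  expect_identical(nrow(edges), 3L)
  expect_true(all(c("degree", "closeness", "betweenness", "level",
                    "community") %in% names(nodes)))
  expect_setequal(edges$metabolite, c("M1", "M2"))
})
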