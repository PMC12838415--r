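# Bipartite metabolite-protein network: construction from tiered
# associations, centralities and centrality levels, Jaccard similarity,
# community detection, hub selection and the capped display subgraph.

#' Build the bipartite metabolite-protein network
#'
#' Unweighted, undirected graph with one edge per unique tier-filtered
#' association. Optional node filters keep the induced subgraph on edges
#' touching at least one listed node of the matching type (plus their
#' partners); nodes left without edges are dropped.
#'
#' @param assocs a `bm_associations` table (see [merge_association_rows()]).
#' @param min_tier minimum evidence tier for an edge (default 1 = all).
#' @param metabolites,proteins optional character vectors restricting the
#'   network to edges touching these nodes.
#' @return an `igraph` graph with vertex attribute `type` of value
#'   `"metabolite"` or `"protein"` and edge attribute `tier`.
#' @export
build_network <- function(assocs, min_tier = 1, metabolites = NULL,
                          proteins = NULL) {
  edges <- filter_by_evidence(assocs, min_tier)
  if (!is.null(metabolites) || !is.null(proteins)) {
    keep <- rep(FALSE, nrow(edges))
    if (!is.null(metabolites)) keep <- keep | edges$metabolite %in% metabolites
    if (!is.null(proteins)) keep <- keep | edges$protein %in% proteins
    edges <- edges[keep, , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    stop("no association passes the tier/node filters; network is empty",
         call. = FALSE)
  }
  # metabolite and protein key spaces may collide textually; prefix internally
  m_ids <- paste0("m:", edges$metabolite)
  p_ids <- paste0("p:", edges$protein)
  g <- igraph::graph_from_edgelist(cbind(m_ids, p_ids), directed = FALSE)
  g <- igraph::set_edge_attr(g, "tier", value = edges$tier)
  vn <- igraph::V(g)$name
  g <- igraph::set_vertex_attr(g, "type",
                               value = ifelse(startsWith(vn, "m:"),
                                              "metabolite", "protein"))
  g <- igraph::set_vertex_attr(g, "label", value = substring(vn, 3))
  g
}

# Display name (without the internal m:/p: prefix) -> vertex name.
node_key <- function(network, node, type = NULL) {
  vn <- igraph::V(network)$name
  cand <- c(node, paste0("m:", node), paste0("p:", node))
  hit <- cand[cand %in% vn]
  if (length(hit) == 0) stop(sprintf("node '%s' not in network", node),
                             call. = FALSE)
  hit[[1]]
}

#' Node centralities of the network
#'
#' Degree (edge count), classic closeness normalized by component size minus
#' one (computed within each connected component, so values stay in
#' `[0, 1]`), and unnormalized shortest-path betweenness. Centrality levels
#' from [centrality_levels()] are attached per partition side (metabolites
#' and proteins are leveled against their own kind).
#'
#' @param network an `igraph` graph from [build_network()].
#' @return data frame of class `bm_centrality`: `node`, `type`, `degree`,
#'   `closeness`, `betweenness`, `level`.
#' @export
centrality <- function(network) {
  if (igraph::vcount(network) == 0) stop("network is empty", call. = FALSE)
  deg <- igraph::degree(network)
  clo <- suppressWarnings(igraph::closeness(network, normalized = TRUE))
  btw <- igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  out <- data.frame(node = igraph::V(network)$label,
                    type = igraph::V(network)$type,
                    degree = as.integer(deg),
                    closeness = as.numeric(clo),
                    betweenness = as.numeric(btw),
                    level = NA_character_,
                    stringsAsFactors = FALSE)
  for (side in unique(out$type)) {
    idx <- which(out$type == side & out$degree >= 1)
    if (length(idx) > 0) out$level[idx] <- centrality_levels(out$degree[idx])
  }
  rownames(out) <- NULL
  class(out) <- c("bm_centrality", "data.frame")
  out
}

#' Centrality levels from a degree vector
#'
#' Degrees are taken to log2 scale; a node is `High` when its score strictly
#' exceeds `median + 2 x MAD`, `Medium` when it exceeds `median + 1 x MAD`
#' (but not the High cutoff), else `Low`. MAD is the unscaled median
#' absolute deviation (no consistency factor).
#'
#' @param degrees integer vector of degrees (all >= 1).
#' @return character vector of levels, same length/order as `degrees`.
#' @export
centrality_levels <- function(degrees) {
  if (length(degrees) == 0) stop("degree vector is empty", call. = FALSE)
  if (any(degrees < 1)) stop("degrees must be >= 1", call. = FALSE)
  s <- log2(degrees)
  med <- stats::median(s)
  mad0 <- stats::median(abs(s - med))
  ifelse(s > med + 2 * mad0, "High",
         ifelse(s > med + 1 * mad0, "Medium", "Low"))
}

#' Jaccard similarity of two same-side nodes
#'
#' `|N(a) intersect N(b)| / |N(a) union N(b)|` over network neighborhoods;
#' 0 when both neighborhoods are empty. Comparing a metabolite with a
#' protein is rejected: neighborhoods of opposite sides live in different
#' node spaces.
#'
#' @param network an `igraph` graph from [build_network()].
#' @param a,b node names (bare metabolite or protein keys).
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(network, a, b) {
  ka <- node_key(network, a); kb <- node_key(network, b)
  ta <- igraph::vertex_attr(network, "type", ka)
  tb <- igraph::vertex_attr(network, "type", kb)
  if (!identical(ta, tb)) {
    stop("Jaccard similarity is defined within one partition side only",
         call. = FALSE)
  }
  na <- igraph::neighbors(network, ka)$name
  nb <- igraph::neighbors(network, kb)$name
  u <- union(na, nb)
  if (length(u) == 0) return(0)
  length(intersect(na, nb)) / length(u)
}

#' Community detection on the network
#'
#' Modularity-optimizing partition via the Louvain algorithm (default
#' resolution 1.5, seeded for reproducibility) or the deterministic greedy
#' modularity method (`resolution` ignored there: the greedy optimizer works
#' on plain modularity).
#'
#' @param network an `igraph` graph from [build_network()].
#' @param method `louvain` or `greedy`.
#' @param resolution Louvain resolution parameter (default 1.5).
#' @param seed integer RNG seed for Louvain (default 0).
#' @return list of class `bm_communities` with `assignment` (named integer
#'   vector over bare node names), `modularity`, `method`, `resolution`,
#'   `seed`.
#' @export
detect_communities <- function(network, method = c("louvain", "greedy"),
                               resolution = 1.5, seed = 0) {
  method <- match.arg(method)
  if (method == "louvain") {
    set.seed(seed)
    comm <- igraph::cluster_louvain(network, resolution = resolution)
  } else {
    comm <- igraph::cluster_fast_greedy(network)
  }
  assignment <- stats::setNames(as.integer(igraph::membership(comm)),
                                igraph::V(network)$label)
  structure(list(assignment = assignment,
                 modularity = igraph::modularity(network,
                                                 igraph::membership(comm)),
                 method = method, resolution = resolution,
                 seed = as.integer(seed)),
            class = "bm_communities")
}

# Top-k selection where a tie group counts as a whole: a node is in the top
# k iff at most k nodes have a value >= its own (max-rank <= k), so a tie
# group qualifies only when it fits inside the top k entirely. When even the
# leading tie group exceeds k (every candidate tied), that group is returned
# and flagged degenerate.
top_k_whole_ties <- function(values, k) {
  n_geq <- vapply(values, function(v) sum(values >= v), integer(1))
  sel <- n_geq <= k
  degenerate <- FALSE
  if (!any(sel) && length(values) > 0) {
    sel <- values == max(values)
    degenerate <- TRUE
  }
  list(sel = sel, degenerate = degenerate)
}

#' Hub nodes and default display selections
#'
#' Hubs are the nodes ranking in the top 5 by degree AND in the top 5 by
#' closeness. A group of tied nodes is admitted only when the whole group
#' fits within the top 5, so the center of a star is its unique hub; when
#' every node ties (e.g. a cycle) the full tie group is returned and flagged
#' degenerate. The default display selection is the top 10 proteins by
#' degree (closeness breaking ties) plus, when query metabolites are
#' supplied, the 5 metabolites most similar (maximum Jaccard) to any query
#' metabolite.
#'
#' @param network an `igraph` graph from [build_network()].
#' @param records a `bm_centrality` table from [centrality()].
#' @param query_metabolites optional character vector of metabolite keys to
#'   anchor the Jaccard-similar display metabolites.
#' @return list of class `bm_hub_report`: `hubs` (character), `degenerate`
#'   (logical: every node tied), `display_proteins`, `display_metabolites`.
#' @export
select_hubs <- function(network, records, query_metabolites = NULL) {
  in_deg <- top_k_whole_ties(records$degree, 5)
  in_clo <- top_k_whole_ties(records$closeness, 5)
  hubs <- records$node[in_deg$sel & in_clo$sel]
  degenerate <- in_deg$degenerate || in_clo$degenerate
  if (degenerate) {
    bm_log("hub selection degenerate: all nodes tie on degree and closeness",
           level = "warn")
  }
  prot <- records[records$type == "protein", , drop = FALSE]
  prot <- prot[order(-prot$degree, -prot$closeness, prot$node), , drop = FALSE]
  display_proteins <- utils::head(prot$node, 10)

  display_metabolites <- character()
  if (!is.null(query_metabolites) && length(query_metabolites) > 0) {
    mets <- setdiff(records$node[records$type == "metabolite"],
                    query_metabolites)
    if (length(mets) > 0) {
      simmax <- vapply(mets, function(m) {
        max(vapply(query_metabolites, function(q)
          jaccard_similarity(network, m, q), numeric(1)))
      }, numeric(1))
      ord <- order(-simmax, mets)
      display_metabolites <- mets[utils::head(ord, 5)]
    }
  }
  structure(list(hubs = sort(hubs), degenerate = degenerate,
                 display_proteins = display_proteins,
                 display_metabolites = display_metabolites),
            class = "bm_hub_report")
}

#' Display subgraph capped at a maximum edge count
#'
#' Edges are ranked by (larger endpoint degree, then smaller endpoint
#' degree, both descending, then lexicographic edge name) and added greedily
#' until the cap: edges incident to hubs therefore enter first, mirroring a
#' display that prioritizes hub metabolites and proteins.
#'
#' @param network an `igraph` graph from [build_network()].
#' @param records a `bm_centrality` table (used for degrees).
#' @param max_edges edge cap (default 100).
#' @return an `igraph` subgraph of `network`.
#' @export
display_subgraph <- function(network, records, max_edges = 100) {
  stopifnot(max_edges >= 0)
  el <- igraph::as_edgelist(network)
  if (nrow(el) <= max_edges) return(network)
  deg <- igraph::degree(network)
  d1 <- deg[el[, 1]]; d2 <- deg[el[, 2]]
  hi <- pmax(d1, d2); lo <- pmin(d1, d2)
  lab <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  ord <- order(-hi, -lo, lab)
  keep <- ord[seq_len(max_edges)]
  sub <- igraph::subgraph_from_edges(network, igraph::E(network)[keep],
                                     delete.vertices = TRUE)
  sub
}

#' Neighbor labels of a node
#'
#' @param network an `igraph` graph from [build_network()].
#' @param node bare metabolite or protein key.
#' @return character vector of neighboring node keys (bare labels).
#' @export
network_neighbors <- function(network, node) {
  nb <- igraph::neighbors(network, node_key(network, node))$name
  substring(nb, 3)
}

#' Write node and edge tables for a network
#'
#' @param network an `igraph` graph from [build_network()].
#' @param records a `bm_centrality` table.
#' @param communities optional `bm_communities`.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return character vector of the written paths, invisibly.
#' @export
write_network <- function(network, records, communities = NULL, prefix) {
  nodes <- as.data.frame(records)
  if (!is.null(communities)) {
    nodes$community <- communities$assignment[nodes$node]
  }
  el <- igraph::as_edgelist(network)
  edges <- data.frame(metabolite = substring(el[, 1], 3),
                      protein = substring(el[, 2], 3),
                      tier = igraph::E(network)$tier,
                      stringsAsFactors = FALSE)
  swap <- startsWith(el[, 1], "p:")
  if (any(swap)) {
    tmp <- edges$metabolite[swap]
    edges$metabolite[swap] <- edges$protein[swap]
    edges$protein[swap] <- tmp
  }
  paths <- c(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"))
  write_tsv_strict(nodes, paths[1])
  write_tsv_strict(edges, paths[2])
  invisible(paths)
}
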