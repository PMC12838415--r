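# Seeded synthetic-data generators for every input the analysis modules
# consume, with planted ground truth (enriched terms, hub proteins,
# tissue-relevant metabolites) for calibration and power studies.
#
# Every generator is a pure function of its configuration: the global seed
# is expanded into fixed per-generator substreams, so the catalog drawn for
# a given config never changes when another generator is added or re-run.

# Category proportions matching a curated blood metabolome: lipids dominate,
# followed by xenobiotics and amino acids.
default_category_proportions <- function() {
  counts <- c("Lipid" = 2320, "Xenobiotics" = 724, "Amino acid" = 381,
              "Peptide" = 153, "Carbohydrate" = 112, "Nucleotide" = 95,
              "Cofactors and vitamins" = 73, "Energy" = 19, "Others" = 73)
  counts / sum(counts)
}

# Source mixture matching the observed contribution of correlation,
# curated-database and metabolic-modeling evidence.
default_source_mixture <- function() {
  counts <- c(curated = 48666, modeling = 11905, correlation = 72829)
  counts / sum(counts)
}

#' Synthetic-data configuration
#'
#' One configuration drives all four generators; the `seed` fixes every
#' draw. Category proportions and the association source mixture default to
#' values representative of a curated blood metabolite resource.
#'
#' @param seed integer master seed.
#' @param n_metabolites,n_proteins,n_tissues,n_terms problem sizes.
#' @param category_proportions named numeric vector over the nine
#'   categories, summing to 1.
#' @param term_size_range length-2 integer vector; term sizes are drawn
#'   uniformly from this range.
#' @param planted_terms list of `list(term_id =, size =, delta =)` entries:
#'   terms of controlled size whose members receive a `+delta` score shift
#'   in [generate_ranked_scores()].
#' @param planted_tissue list of `list(metabolite =, tissue =, fold =)`
#'   entries: the metabolite's associated proteins are tissue-elevated and
#'   `fold`-times over-expressed in that tissue in [generate_expression()].
#' @param association_density probability that a (metabolite, protein) pair
#'   carries an association; must lie in `(0, 1]`.
#' @param source_mixture named probabilities over
#'   `curated`/`modeling`/`correlation`, summing to 1.
#' @param validated_fraction fraction of association rows carrying an
#'   independent-validation flag.
#' @param n_hub_proteins number of designated hub proteins whose degree is
#'   forced to ten times the median protein degree.
#' @param ntpm_lognormal length-2 vector `(meanlog, sdlog)` of the baseline
#'   nTPM distribution.
#' @param elevation_rate per-(protein, tissue) probability of background
#'   tissue elevation.
#' @param background_elevation_fold expression multiplier applied to
#'   background-elevated cells.
#' @return list of class `bm_synth_config`.
#' @export
synth_config <- function(seed = 0, n_metabolites = 200, n_proteins = 150,
                         n_tissues = 36, n_terms = 20,
                         category_proportions = default_category_proportions(),
                         term_size_range = c(5, 40),
                         planted_terms = list(), planted_tissue = list(),
                         association_density = 0.05,
                         source_mixture = default_source_mixture(),
                         validated_fraction = 0.05, n_hub_proteins = 0,
                         ntpm_lognormal = c(meanlog = 2, sdlog = 1),
                         elevation_rate = 0.03,
                         background_elevation_fold = 4) {
  stopifnot(n_metabolites >= 1, n_proteins >= 1, n_tissues >= 1, n_terms >= 0,
            abs(sum(category_proportions) - 1) < 1e-8,
            abs(sum(source_mixture) - 1) < 1e-8,
            length(term_size_range) == 2,
            term_size_range[1] <= term_size_range[2])
  if (association_density <= 0 || association_density > 1) {
    stop("association_density must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "bm_synth_config")
}

met_ids <- function(n) sprintf("M%05d", seq_len(n))
prot_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Generate a synthetic metabolite catalog with term sets
#'
#' Categories are sampled from `category_proportions`; each metabolite gets
#' a synthetic name, one synonym and a structured identifier. Terms are
#' drawn without replacement from the catalog at sizes uniform in
#' `term_size_range`; planted terms are created first at their requested
#' sizes.
#'
#' @param config a [synth_config()].
#' @return list with `catalog` (a `bm_catalog`) and `terms` (list of
#'   [term_set()]).
#' @export
generate_catalog <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_metabolites
  ids <- met_ids(n)
  categories <- sample(names(config$category_proportions), n, replace = TRUE,
                       prob = config$category_proportions)
  catalog <- metabolite_catalog(
    hub_id = ids,
    name = paste0("metabolite-", seq_len(n)),
    category = categories,
    synonyms = paste0("syn-", tolower(ids)),
    identifiers = list(HMDB = sprintf("HMDB%07d", seq_len(n)))
  )
  terms <- list()
  for (pt in config$planted_terms) {
    if (pt$size > n) stop("planted term size exceeds n_metabolites", call. = FALSE)
    terms[[pt$term_id]] <- term_set(pt$term_id, sample(ids, pt$size),
                                    annotation_type = "Pathway")
  }
  n_random <- config$n_terms - length(terms)
  if (config$n_terms > 0 && n_random > 0) {
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    n_random, replace = TRUE)
    if (any(sizes > n)) stop("term size exceeds n_metabolites", call. = FALSE)
    types <- sample(ANNOTATION_TYPES, n_random, replace = TRUE)
    for (j in seq_len(n_random)) {
      tid <- sprintf("T%04d", j)
      terms[[tid]] <- term_set(tid, sample(ids, sizes[j]),
                               annotation_type = types[j])
    }
  }
  list(catalog = catalog, terms = unname(terms))
}

#' Generate a synthetic raw association table with planted hubs
#'
#' Each (metabolite, protein) pair carries an association with probability
#' `association_density`; designated hub proteins are afterwards connected
#' to enough random metabolites to reach ten times the median protein
#' degree. Each association row carries one source drawn from
#' `source_mixture` and Bernoulli validation flags.
#'
#' @param config a [synth_config()].
#' @return list with `rows` (raw rows for [merge_association_rows()]) and
#'   `hub_proteins` (character vector of the planted hub keys).
#' @export
generate_associations <- function(config) {
  set.seed(derive_seed(config$seed, 2L))
  mets <- met_ids(config$n_metabolites)
  prots <- prot_ids(config$n_proteins)
  pairs <- expand.grid(metabolite = mets, protein = prots,
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < config$association_density
  edges <- pairs[keep, , drop = FALSE]

  hub_proteins <- character()
  if (config$n_hub_proteins > 0) {
    hub_proteins <- utils::tail(prots, config$n_hub_proteins)
    med_deg <- max(1, stats::median(table(factor(edges$protein, levels = prots))))
    target <- min(config$n_metabolites, ceiling(10 * med_deg))
    for (hp in hub_proteins) {
      partners <- sample(mets, target)
      edges <- rbind(edges[edges$protein != hp, , drop = FALSE],
                     data.frame(metabolite = partners, protein = hp,
                                stringsAsFactors = FALSE))
    }
  }
  n_e <- nrow(edges)
  rows <- data.frame(
    metabolite = edges$metabolite,
    protein = edges$protein,
    source = sample(names(config$source_mixture), n_e, replace = TRUE,
                    prob = config$source_mixture),
    validated_independent = stats::runif(n_e) < config$validated_fraction,
    validated_interaction_db = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  list(rows = rows, hub_proteins = hub_proteins)
}

#' Generate a synthetic tissue expression table with planted elevation
#'
#' Baseline nTPM values are lognormal; a background elevation indicator is
#' drawn per cell at `elevation_rate` and elevated cells are multiplied by
#' `background_elevation_fold`. For every planted (metabolite, tissue, fold)
#' entry, the metabolite's associated proteins (from
#' [generate_associations()] under the same config) are marked elevated in
#' that tissue and their nTPM there is multiplied by `fold`.
#'
#' @param config a [synth_config()].
#' @return a `bm_expression` table.
#' @export
generate_expression <- function(config) {
  for (pt in config$planted_tissue) {
    if (pt$fold <= 1) {
      stop("planted tissue fold must exceed 1 (no signal otherwise)",
           call. = FALSE)
    }
  }
  assoc_partners <- NULL
  if (length(config$planted_tissue) > 0) {
    raw <- generate_associations(config)
    merged <- merge_association_rows(raw$rows)
    assoc_partners <- split(merged$protein, merged$metabolite)
  }
  set.seed(derive_seed(config$seed, 3L))
  prots <- prot_ids(config$n_proteins)
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  ntpm <- matrix(stats::rlnorm(config$n_proteins * config$n_tissues,
                               meanlog = config$ntpm_lognormal[[1]],
                               sdlog = config$ntpm_lognormal[[2]]),
                 config$n_proteins, config$n_tissues,
                 dimnames = list(prots, tissues))
  elevated <- matrix(stats::runif(length(ntpm)) < config$elevation_rate,
                     config$n_proteins, config$n_tissues,
                     dimnames = list(prots, tissues))
  ntpm[elevated] <- ntpm[elevated] * config$background_elevation_fold
  for (pt in config$planted_tissue) {
    partners <- intersect(assoc_partners[[pt$metabolite]] %||% character(),
                          prots)
    if (length(partners) == 0) {
      bm_log(sprintf("planted metabolite %s has no associated proteins",
                     pt$metabolite), level = "warn")
      next
    }
    ntpm[partners, pt$tissue] <- ntpm[partners, pt$tissue] * pt$fold
    elevated[partners, pt$tissue] <- TRUE
  }
  tissue_expression(ntpm, elevated)
}

#' Generate a ranked score list with planted enriched terms
#'
#' Null scores are standard normal; members of every planted term receive a
#' `+delta` shift. The catalog and terms come from [generate_catalog()]
#' under the same config, so the planted terms are guaranteed to exist.
#'
#' @param config a [synth_config()]; `planted_terms` entries must carry a
#'   `delta`.
#' @return list with `ranked` (a `bm_ranked_list`), `catalog` and `terms`
#'   as generated.
#' @export
generate_ranked_scores <- function(config) {
  gen <- generate_catalog(config)
  term_ids <- vapply(gen$terms, `[[`, character(1), "term_id")
  for (pt in config$planted_terms) {
    if (!pt$term_id %in% term_ids) {
      stop(sprintf("planted term %s not present in the generated collection",
                   pt$term_id), call. = FALSE)
    }
  }
  set.seed(derive_seed(config$seed, 4L))
  ids <- gen$catalog$hub_id
  scores <- stats::rnorm(length(ids))
  names(scores) <- ids
  for (pt in config$planted_terms) {
    members <- gen$terms[[match(pt$term_id, term_ids)]]$members
    scores[members] <- scores[members] + pt$delta
  }
  list(ranked = ranked_list(ids, unname(scores)),
       catalog = gen$catalog, terms = gen$terms)
}

#' Write the full set of synthetic fixtures to a directory
#'
#' Emits `catalog.tsv`, `terms.gmt`, `associations.tsv`, `expression.tsv`
#' and `ranked.tsv` so they can be fed back through the package readers or
#' the command-line interface.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_fixtures <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_catalog(config)
  assoc <- generate_associations(config)
  expr <- generate_expression(config)
  paths <- c(catalog = file.path(out_dir, "catalog.tsv"),
             terms = file.path(out_dir, "terms.gmt"),
             associations = file.path(out_dir, "associations.tsv"),
             expression = file.path(out_dir, "expression.tsv"),
             ranked = file.path(out_dir, "ranked.tsv"))
  write_catalog(gen$catalog, paths[["catalog"]])
  write_gmt(gen$terms, paths[["terms"]])
  raw <- assoc$rows
  names(raw)[names(raw) == "metabolite"] <- "metabolite_id"
  names(raw)[names(raw) == "protein"] <- "protein_id"
  raw$validated_independent <- as.integer(raw$validated_independent)
  raw$validated_interaction_db <- as.integer(raw$validated_interaction_db)
  write_tsv_strict(raw, paths[["associations"]])
  long <- data.frame(
    protein_id = rep(expr$proteins, times = length(expr$tissues)),
    tissue = rep(expr$tissues, each = length(expr$proteins)),
    ntpm = as.vector(expr$ntpm),
    elevation_label = ifelse(as.vector(expr$elevated), "tissue enhanced",
                             "none"),
    stringsAsFactors = FALSE
  )
  write_tsv_strict(long, paths[["expression"]])
  if (length(config$planted_terms) > 0 || config$n_terms > 0) {
    rk <- generate_ranked_scores(config)$ranked
    names(rk) <- c("metabolite_id", "score")
    write_tsv_strict(rk, paths[["ranked"]])
  } else {
    paths <- paths[names(paths) != "ranked"]
  }
  invisible(paths)
}
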