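# Metabolite catalog: domain constants, readers, identifier resolution and
# category summaries.

#' The nine metabolite categories
#'
#' Closed set of main chemical/biological categories used to classify blood
#' metabolites.
#'
#' @export
METABOLITE_CATEGORIES <- c(
  "Lipid", "Xenobiotics", "Amino acid", "Peptide", "Carbohydrate",
  "Nucleotide", "Cofactors and vitamins", "Energy", "Others"
)

#' The 17 supported metabolite identifier namespaces
#'
#' `Name/Synonym` covers common names and synonyms (matched
#' case-insensitively); the remaining sixteen are structured registry
#' identifiers (matched case-sensitively).
#'
#' @export
IDENTIFIER_NAMESPACES <- c(
  "Name/Synonym", "HMDB", "KEGG", "BioCyc", "PubChem", "PDB", "ChEBI",
  "DrugBank", "Phenol-Explorer", "FooDB", "KNApSAcK", "Chemspider", "VMH",
  "LipidMaps", "SwissLipids", "SMILES", "InChI Key"
)

# Structured namespaces = everything except the free-text Name/Synonym entry.
structured_namespaces <- function() setdiff(IDENTIFIER_NAMESPACES, "Name/Synonym")

#' Construct a metabolite catalog
#'
#' A catalog is a data frame with one row per curated metabolite: an opaque
#' unique key (`hub_id`), a display `name`, a `category` from the closed
#' nine-value set, pipe-delimited `synonyms`, and one column per structured
#' identifier namespace (empty string = no identifier in that namespace).
#'
#' @param hub_id character vector of unique keys.
#' @param name character vector of primary names.
#' @param category character vector; each value must be one of
#'   [METABOLITE_CATEGORIES].
#' @param synonyms character vector of pipe-delimited synonym lists
#'   (may be empty strings).
#' @param identifiers optional data frame (or named list of character
#'   vectors) of structured identifiers, one column per namespace.
#' @return a `data.frame` of class `bm_catalog`.
#' @export
metabolite_catalog <- function(hub_id, name, category,
                               synonyms = rep("", length(hub_id)),
                               identifiers = NULL) {
  hub_id <- as.character(hub_id)
  if (anyDuplicated(hub_id)) {
    stop("hub_id values must be unique within a catalog", call. = FALSE)
  }
  bad <- setdiff(unique(category), METABOLITE_CATEGORIES)
  if (length(bad) > 0) {
    stop(sprintf("unknown metabolite category: %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(METABOLITE_CATEGORIES, collapse = ", ")), call. = FALSE)
  }
  cat_df <- data.frame(hub_id = hub_id, name = as.character(name),
                       category = as.character(category),
                       synonyms = as.character(synonyms),
                       check.names = FALSE, stringsAsFactors = FALSE)
  for (ns in structured_namespaces()) {
    col <- if (!is.null(identifiers) && ns %in% names(identifiers)) {
      as.character(identifiers[[ns]])
    } else {
      rep("", nrow(cat_df))
    }
    cat_df[[ns]] <- col
  }
  if (!is.null(identifiers)) {
    unknown <- setdiff(names(identifiers), structured_namespaces())
    if (length(unknown) > 0) {
      stop(sprintf("unknown identifier namespace(s): %s; valid namespaces are: %s",
                   paste(unknown, collapse = ", "),
                   paste(IDENTIFIER_NAMESPACES, collapse = ", ")), call. = FALSE)
    }
  }
  class(cat_df) <- c("bm_catalog", "data.frame")
  cat_df
}

#' Read a metabolite catalog from TSV
#'
#' Expects columns `hub_id`, `name`, `category`, `synonyms` (pipe-delimited)
#' and optionally one column per structured namespace. Malformed rows
#' (duplicate keys, unknown categories) are rejected with the offending line
#' numbers.
#'
#' @param path path to the TSV file.
#' @return a `bm_catalog`.
#' @export
read_catalog <- function(path) {
  df <- read_tsv_strict(path, required_cols = c("hub_id", "name", "category"),
                        what = "catalog")
  if (!"synonyms" %in% names(df)) df$synonyms <- ""
  dup <- duplicated(df$hub_id)
  if (any(dup)) {
    stop(sprintf("catalog %s: duplicate hub_id at line(s) %s", path,
                 paste(which(dup) + 1L, collapse = ", ")), call. = FALSE)
  }
  badcat <- !(df$category %in% METABOLITE_CATEGORIES)
  if (any(badcat)) {
    stop(sprintf("catalog %s: unknown category at line(s) %s", path,
                 paste(which(badcat) + 1L, collapse = ", ")), call. = FALSE)
  }
  ids <- df[intersect(names(df), structured_namespaces())]
  metabolite_catalog(df$hub_id, df$name, df$category, df$synonyms,
                     identifiers = if (ncol(ids)) ids else NULL)
}

#' Write a metabolite catalog to TSV
#'
#' @param catalog a `bm_catalog`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv_strict(as.data.frame(catalog), path)
}

# Split a pipe-delimited synonym string into a trimmed character vector.
split_synonyms <- function(x) {
  out <- strsplit(x, "|", fixed = TRUE)
  lapply(out, function(s) trimws(s[nzchar(trimws(s))]))
}

#' Resolve a metabolite identifier to catalog keys
#'
#' With an explicit `namespace`, performs an exact match within that
#' namespace (case-insensitive for `Name/Synonym`, case-preserving for
#' structured registry identifiers). Without one, searches names and
#' synonyms first (case-insensitively) and falls back to all structured
#' namespaces only when no name/synonym hit exists. Ambiguous matches are
#' all returned, sorted by `hub_id`, and flagged in the log.
#'
#' @param catalog a `bm_catalog`.
#' @param query identifier string to look up.
#' @param namespace optional namespace name, one of [IDENTIFIER_NAMESPACES].
#' @return character vector of matching `hub_id`s (possibly empty).
#' @export
resolve_identifier <- function(catalog, query, namespace = NULL) {
  stopifnot(is.character(query), length(query) == 1L)
  name_syn_match <- function() {
    q <- tolower(query)
    syns <- split_synonyms(catalog$synonyms)
    hit <- tolower(catalog$name) == q |
      vapply(syns, function(s) q %in% tolower(s), logical(1))
    catalog$hub_id[hit]
  }
  if (!is.null(namespace)) {
    if (!namespace %in% IDENTIFIER_NAMESPACES) {
      stop(sprintf("unknown namespace '%s'; the valid namespaces are: %s",
                   namespace, paste(IDENTIFIER_NAMESPACES, collapse = ", ")),
           call. = FALSE)
    }
    hits <- if (namespace == "Name/Synonym") {
      name_syn_match()
    } else {
      catalog$hub_id[nzchar(catalog[[namespace]]) & catalog[[namespace]] == query]
    }
  } else {
    hits <- name_syn_match()
    if (length(hits) == 0) {
      hit_rows <- rep(FALSE, nrow(catalog))
      for (ns in structured_namespaces()) {
        hit_rows <- hit_rows | (nzchar(catalog[[ns]]) & catalog[[ns]] == query)
      }
      hits <- catalog$hub_id[hit_rows]
    }
  }
  hits <- sort(unique(hits))
  if (length(hits) > 1) {
    bm_log(sprintf("query '%s' is ambiguous: %d matching metabolites", query,
                   length(hits)), level = "warn")
  }
  hits
}

#' Summarize a catalog by category
#'
#' Counts metabolites per category and reports percentage shares rounded
#' half-up to two decimals.
#'
#' @param catalog a `bm_catalog` (or any data frame with a `category`
#'   column drawn from the nine-category set).
#' @return list of class `bm_category_summary` with `counts` (named integer
#'   vector over all nine categories), `total` and `percentages`.
#' @export
summarize_catalog <- function(catalog) {
  if (nrow(catalog) == 0) stop("cannot summarize an empty catalog", call. = FALSE)
  counts <- table(factor(catalog$category, levels = METABOLITE_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  stopifnot(total == nrow(catalog))
  pct <- round_half_up(100 * counts / total, 2)
  structure(list(counts = counts, total = total, percentages = pct),
            class = "bm_category_summary")
}

#' @export
print.bm_category_summary <- function(x, ...) {
  cat(sprintf("Catalog summary: %d metabolites\n", x$total))
  for (k in names(x$counts)) {
    if (x$counts[[k]] > 0) {
      cat(sprintf("  %-24s %6d  (%.2f%%)\n", k, x$counts[[k]], x$percentages[[k]]))
    }
  }
  invisible(x)
}
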