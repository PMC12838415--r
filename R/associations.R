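# Metabolite-protein associations: provenance storage, three-tier evidence
# classification, filtering and bookkeeping summaries.

ASSOCIATION_SOURCES <- c("curated", "modeling", "correlation")

#' Assign the evidence tier of a metabolite-protein association
#'
#' Three-level confidence scheme: Tier 3 (validated evidence) when the
#' association is supported by at least two different approaches or by
#' independent validation (an independent cohort or an external interaction
#' database); Tier 2 (curated evidence) when the only support is a manually
#' curated database; Tier 1 (inferred evidence) when the association comes
#' solely from computational modeling and/or statistical correlation.
#'
#' @param sources character vector (treated as a set) drawn from
#'   `curated`, `modeling`, `correlation`; must be non-empty.
#' @param validated_independent logical; independent-cohort support.
#' @param validated_interaction_db logical; interaction-database support.
#' @return integer tier in `1:3`.
#' @export
assign_tier <- function(sources, validated_independent = FALSE,
                        validated_interaction_db = FALSE) {
  sources <- unique(as.character(sources))
  if (length(sources) == 0) stop("sources must be non-empty", call. = FALSE)
  bad <- setdiff(sources, ASSOCIATION_SOURCES)
  if (length(bad) > 0) {
    stop(sprintf("unrecognized source token(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(ASSOCIATION_SOURCES, collapse = ", ")), call. = FALSE)
  }
  if (length(sources) >= 2 || isTRUE(validated_independent) ||
      isTRUE(validated_interaction_db)) {
    return(3L)
  }
  if (identical(sources, "curated")) return(2L)
  1L
}

# Vectorized tier assignment on the merged logical-flag representation.
assign_tier_vec <- function(curated, modeling, correlation,
                            validated_independent, validated_interaction_db) {
  n_src <- curated + modeling + correlation
  if (any(n_src == 0)) stop("sources must be non-empty", call. = FALSE)
  tier <- rep(1L, length(n_src))
  tier[curated & n_src == 1] <- 2L
  tier[n_src >= 2 | validated_independent | validated_interaction_db] <- 3L
  tier
}

#' Merge raw association rows into unique tiered associations
#'
#' Input rows carry one source each; rows are grouped by
#' `(metabolite, protein)`, sources are unioned, validation flags are OR-ed,
#' and the evidence tier is assigned on the merged record.
#'
#' @param rows data frame with columns `metabolite`, `protein`, `source`
#'   and optionally `validated_independent`, `validated_interaction_db`
#'   (0/1 or logical; absent = 0).
#' @return data frame of class `bm_associations`: one row per unique pair
#'   with logical source columns, validation flags and a `tier` column.
#' @export
merge_association_rows <- function(rows) {
  req <- c("metabolite", "protein", "source")
  missing <- setdiff(req, names(rows))
  if (length(missing) > 0) {
    stop(sprintf("association rows missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- !(rows$source %in% ASSOCIATION_SOURCES)
  if (any(bad)) {
    stop(sprintf("unrecognized source token(s): %s (valid: %s)",
                 paste(unique(rows$source[bad]), collapse = ", "),
                 paste(ASSOCIATION_SOURCES, collapse = ", ")), call. = FALSE)
  }
  vi <- if ("validated_independent" %in% names(rows)) {
    as.logical(rows$validated_independent)
  } else rep(FALSE, nrow(rows))
  vd <- if ("validated_interaction_db" %in% names(rows)) {
    as.logical(rows$validated_interaction_db)
  } else rep(FALSE, nrow(rows))

  key <- paste(rows$metabolite, rows$protein, sep = "\r")
  grp <- match(key, unique(key))
  # rowsum is C-level and keeps groups in first-occurrence (numeric) order
  agg_or <- function(x) rowsum(as.integer(x), grp)[, 1] > 0L
  first <- !duplicated(grp)
  out <- data.frame(
    metabolite = rows$metabolite[first],
    protein = rows$protein[first],
    curated = agg_or(rows$source == "curated"),
    modeling = agg_or(rows$source == "modeling"),
    correlation = agg_or(rows$source == "correlation"),
    validated_independent = agg_or(vi),
    validated_interaction_db = agg_or(vd),
    stringsAsFactors = FALSE
  )
  out$tier <- assign_tier_vec(out$curated, out$modeling, out$correlation,
                              out$validated_independent,
                              out$validated_interaction_db)
  rownames(out) <- NULL
  class(out) <- c("bm_associations", "data.frame")
  out
}

#' Filter associations by evidence level
#'
#' @param assocs a `bm_associations` table.
#' @param min_tier minimum evidence tier to keep (1, 2 or 3).
#' @return the filtered table, input order preserved.
#' @export
filter_by_evidence <- function(assocs, min_tier) {
  if (!is.numeric(min_tier) || length(min_tier) != 1 || !min_tier %in% 1:3) {
    stop("min_tier must be 1, 2 or 3", call. = FALSE)
  }
  assocs[assocs$tier >= min_tier, , drop = FALSE]
}

#' Summarize an association table
#'
#' Counts per evidence tier and per source, plus the numbers of distinct
#' metabolites and proteins. Source percentages (one decimal, half-up) are
#' computed against the total number of unique associations; an association
#' with multiple sources is counted once under each.
#'
#' @param assocs a `bm_associations` table.
#' @return list of class `bm_association_summary`.
#' @export
summarize_associations <- function(assocs) {
  if (nrow(assocs) == 0) stop("cannot summarize an empty association table",
                              call. = FALSE)
  n_total <- nrow(assocs)
  n_per_source <- c(curated = sum(assocs$curated),
                    modeling = sum(assocs$modeling),
                    correlation = sum(assocs$correlation))
  n_per_tier <- stats::setNames(
    as.integer(table(factor(assocs$tier, levels = 1:3))),
    c("1", "2", "3"))
  structure(list(
    n_total = n_total,
    n_per_source = n_per_source,
    n_per_tier = n_per_tier,
    n_metabolites = length(unique(assocs$metabolite)),
    n_proteins = length(unique(assocs$protein)),
    percent_per_source = round_half_up(100 * n_per_source / n_total, 1)
  ), class = "bm_association_summary")
}

#' @export
print.bm_association_summary <- function(x, ...) {
  cat(sprintf("%d associations between %d metabolites and %d proteins\n",
              x$n_total, x$n_metabolites, x$n_proteins))
  cat(sprintf("  tiers: 1=%d 2=%d 3=%d\n",
              x$n_per_tier[["1"]], x$n_per_tier[["2"]], x$n_per_tier[["3"]]))
  for (s in names(x$n_per_source)) {
    cat(sprintf("  %-11s %7d (%.1f%%)\n", s, x$n_per_source[[s]],
                x$percent_per_source[[s]]))
  }
  invisible(x)
}

#' Read raw association rows from TSV and merge them
#'
#' Expected columns: `metabolite_id`, `protein_id`, `source`, and optional
#' 0/1 columns `validated_independent`, `validated_interaction_db`.
#'
#' @param path path to the TSV file.
#' @return a merged `bm_associations` table (see [merge_association_rows()]).
#' @export
read_associations <- function(path) {
  df <- read_tsv_strict(path, required_cols = c("metabolite_id", "protein_id",
                                                "source"),
                        what = "association")
  names(df)[names(df) == "metabolite_id"] <- "metabolite"
  names(df)[names(df) == "protein_id"] <- "protein"
  merge_association_rows(df)
}

#' Write a merged association table (with tiers) to TSV
#'
#' @param assocs a `bm_associations` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_associations <- function(assocs, path) {
  write_tsv_strict(as.data.frame(assocs), path)
}
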