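# Tissue-relevance analysis: three complementary criteria on the expression
# of a metabolite's associated proteins across tissues, an eligibility
# filter, reliability stratification, and tissue enrichment of query lists.

#' Construct a tissue expression table
#'
#' Holds a protein x tissue matrix of nTPM values together with a logical
#' elevation matrix. "Tissue elevated" is the umbrella over the labels
#' `tissue enriched`, `tissue enhanced` and `group enriched`; the label
#' `none` (or an empty string) means not elevated. A protein is "detected"
#' in a tissue when its nTPM exceeds 1.
#'
#' @param ntpm numeric matrix (proteins x tissues) of non-negative nTPM
#'   values with row and column names.
#' @param elevation logical matrix of the same shape: is the protein
#'   tissue-elevated in that tissue?
#' @return list of class `bm_expression` with `ntpm`, `elevated`,
#'   `proteins`, `tissues`.
#' @export
tissue_expression <- function(ntpm, elevation) {
  stopifnot(is.matrix(ntpm), is.matrix(elevation),
            identical(dim(ntpm), dim(elevation)))
  if (is.null(rownames(ntpm)) || is.null(colnames(ntpm))) {
    stop("ntpm matrix must carry protein rownames and tissue colnames",
         call. = FALSE)
  }
  if (any(!is.finite(ntpm)) || any(ntpm < 0)) {
    stop("nTPM values must be finite and non-negative", call. = FALSE)
  }
  mode(elevation) <- "logical"
  if (anyNA(elevation)) stop("elevation must be defined for every cell",
                             call. = FALSE)
  dimnames(elevation) <- dimnames(ntpm)
  structure(list(ntpm = ntpm, elevated = elevation,
                 proteins = rownames(ntpm), tissues = colnames(ntpm)),
            class = "bm_expression")
}

ELEVATION_LABELS <- c("tissue enriched", "tissue enhanced", "group enriched",
                      "none")

#' Read a long-format tissue expression TSV
#'
#' Columns: `protein_id`, `tissue`, `ntpm`, `elevation_label` (one of
#' `tissue enriched`, `tissue enhanced`, `group enriched`, `none`).
#'
#' @param path path to the TSV file.
#' @return a `bm_expression`.
#' @export
read_expression <- function(path) {
  df <- read_tsv_strict(path, required_cols = c("protein_id", "tissue", "ntpm",
                                                "elevation_label"),
                        what = "expression")
  bad <- !(df$elevation_label %in% ELEVATION_LABELS | df$elevation_label == "")
  if (any(bad)) {
    stop(sprintf("expression %s: invalid elevation label at line(s) %s", path,
                 paste(utils::head(which(bad), 10) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  proteins <- unique(df$protein_id)
  tissues <- unique(df$tissue)
  ntpm <- matrix(NA_real_, length(proteins), length(tissues),
                 dimnames = list(proteins, tissues))
  elev <- matrix(FALSE, length(proteins), length(tissues),
                 dimnames = list(proteins, tissues))
  ntpm[cbind(df$protein_id, df$tissue)] <- as.numeric(df$ntpm)
  elev[cbind(df$protein_id, df$tissue)] <-
    df$elevation_label %in% ELEVATION_LABELS[1:3]
  if (anyNA(ntpm)) {
    stop(sprintf("expression %s: incomplete protein x tissue grid", path),
         call. = FALSE)
  }
  tissue_expression(ntpm, elev)
}

#' Criterion 1: tissue-elevated proteins over-represented among partners
#'
#' One-sided Fisher's exact test on the 2x2 table (associated vs not) x
#' (tissue-elevated vs not) over the protein universe. Significant at
#' p < 0.05.
#'
#' @param assoc_proteins character vector of the metabolite's associated
#'   proteins (subset of `universe`).
#' @param tissue tissue name present in `table`.
#' @param table a `bm_expression`.
#' @param universe character vector of background proteins.
#' @return list with `p` and logical `flag`.
#' @export
criterion1_overrepresentation <- function(assoc_proteins, tissue, table,
                                          universe) {
  if (!tissue %in% table$tissues) {
    stop(sprintf("tissue '%s' not present in the expression table", tissue),
         call. = FALSE)
  }
  universe <- unique(universe)
  assoc_proteins <- intersect(unique(assoc_proteins), universe)
  elevated <- intersect(table$proteins[table$elevated[, tissue]], universe)
  k <- length(intersect(assoc_proteins, elevated))
  p <- fisher_enrichment(k, length(assoc_proteins), length(elevated),
                         length(universe))
  list(p = p, flag = p < 0.05)
}

#' Criterion 2: tissue-elevated partner count above the CI upper bound
#'
#' The per-tissue counts of associated tissue-elevated proteins are treated
#' as a sample; a tissue is flagged when its count strictly exceeds
#' `mean + 1.96 x sample SD` (a normal-theory 95% envelope).
#'
#' @param counts numeric vector with one entry per tissue.
#' @return list with `upper_bound` and logical `flags` (named as `counts`).
#' @export
criterion2_count_outlier <- function(counts) {
  if (length(counts) < 2) {
    stop("criterion 2 needs counts for at least two tissues", call. = FALSE)
  }
  upper <- mean(counts) + 1.96 * stats::sd(counts)
  list(upper_bound = upper, flags = counts > upper)
}

#' Criterion 3: partner expression elevated relative to other tissues
#'
#' Restricted to associated proteins detected in the tissue (nTPM > 1), a
#' paired one-sided Wilcoxon signed-rank test compares each protein's nTPM
#' in the tissue against that protein's median nTPM across all other
#' tissues. Zero differences are dropped; the exact distribution is used for
#' up to 25 non-zero pairs and the normal approximation above that. Fewer
#' than two detected proteins yields a missing p and a FALSE flag.
#'
#' @inheritParams criterion1_overrepresentation
#' @return list with `p` (possibly `NA`), logical `flag` and `n_detected`.
#' @export
criterion3_expression_elevation <- function(assoc_proteins, tissue, table) {
  if (!tissue %in% table$tissues) {
    stop(sprintf("tissue '%s' not present in the expression table", tissue),
         call. = FALSE)
  }
  prots <- intersect(unique(assoc_proteins), table$proteins)
  x <- table$ntpm[prots, tissue, drop = TRUE]
  detected <- prots[x > 1]
  if (length(detected) < 2) {
    bm_log(sprintf("criterion 3 (%s): %d detected partner(s); p undefined",
                   tissue, length(detected)))
    return(list(p = NA_real_, flag = FALSE, n_detected = length(detected)))
  }
  others <- setdiff(table$tissues, tissue)
  baseline <- apply(table$ntpm[detected, others, drop = FALSE], 1,
                    stats::median)
  d <- table$ntpm[detected, tissue] - baseline
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(p = NA_real_, flag = FALSE, n_detected = length(detected)))
  }
  p <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater",
                       exact = length(d) <= 25, correct = TRUE)$p.value)
  list(p = p, flag = is.finite(p) && p < 0.05, n_detected = length(detected))
}

#' Call tissue relevance for one metabolite
#'
#' Per tissue, the metabolite is eligible when at least three of its
#' associated proteins are tissue-elevated there; ineligible tissues are
#' never evaluated (avoiding spurious calls from tiny protein sets). For
#' eligible tissues the three criteria are applied and the per-tissue
#' category is `Tissue Relevant` when at least one holds, otherwise
#' `Low tissue relevance`; ineligible tissues are `Unknown`. Reliability of
#' a `Tissue Relevant` call: `High` when all three criteria hold, `Medium`
#' for two criteria or one criterion plus external localization support for
#' that tissue, `Low` for a single unsupported criterion.
#'
#' @param metabolite metabolite key (carried through to the output).
#' @param assoc_proteins character vector of the metabolite's associated
#'   proteins.
#' @param table a `bm_expression`.
#' @param universe background protein universe for criterion 1 (defaults to
#'   all proteins in `table`).
#' @param hmdb_localizations optional character vector of tissues with
#'   curated localization support for this metabolite.
#' @return data frame of class `bm_relevance_calls`, one row per tissue:
#'   `metabolite`, `tissue`, `eligible`, `c1_p`, `c1`, `c2_count`,
#'   `c2_upper`, `c2`, `c3_p`, `c3`, `n_criteria`, `hmdb_support`,
#'   `category`, `reliability`.
#' @export
call_tissue_relevance <- function(metabolite, assoc_proteins, table,
                                  universe = table$proteins,
                                  hmdb_localizations = NULL) {
  tissues <- table$tissues
  assoc_proteins <- intersect(unique(assoc_proteins), table$proteins)
  n_t <- length(tissues)

  # counts of associated tissue-elevated proteins, one per tissue
  counts <- if (length(assoc_proteins) > 0) {
    colSums(table$elevated[assoc_proteins, , drop = FALSE])
  } else {
    stats::setNames(rep(0, n_t), tissues)
  }
  eligible <- counts >= 3
  c2 <- criterion2_count_outlier(counts)

  out <- data.frame(metabolite = metabolite, tissue = tissues,
                    eligible = as.vector(eligible),
                    c1_p = NA_real_, c1 = FALSE,
                    c2_count = as.vector(counts), c2_upper = c2$upper_bound,
                    c2 = FALSE, c3_p = NA_real_, c3 = FALSE,
                    n_criteria = 0L,
                    hmdb_support = tissues %in% (hmdb_localizations %||% character()),
                    category = "Unknown", reliability = "n/a",
                    stringsAsFactors = FALSE)

  for (i in seq_len(n_t)) {
    if (!out$eligible[i]) next
    ts <- tissues[i]
    r1 <- criterion1_overrepresentation(assoc_proteins, ts, table, universe)
    r3 <- criterion3_expression_elevation(assoc_proteins, ts, table)
    out$c1_p[i] <- r1$p; out$c1[i] <- r1$flag
    out$c2[i] <- c2$flags[[i]]
    out$c3_p[i] <- r3$p; out$c3[i] <- r3$flag
    out$n_criteria[i] <- sum(out$c1[i], out$c2[i], out$c3[i])
    if (out$n_criteria[i] >= 1) {
      out$category[i] <- "Tissue Relevant"
      out$reliability[i] <- if (out$n_criteria[i] == 3) {
        "High"
      } else if (out$n_criteria[i] == 2 ||
                 (out$n_criteria[i] == 1 && out$hmdb_support[i])) {
        "Medium"
      } else {
        "Low"
      }
    } else {
      out$category[i] <- "Low tissue relevance"
    }
  }
  rownames(out) <- NULL
  class(out) <- c("bm_relevance_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize tissue-relevance calls
#'
#' Counts metabolite-tissue pairs by category and, within `Tissue Relevant`
#' pairs, by reliability; also reports the per-metabolite category (a
#' metabolite is `Tissue Relevant` if any tissue is, `Low tissue relevance`
#' if it has eligible tissues but none passes, else `Unknown`).
#'
#' @param calls a `bm_relevance_calls` table (rows from one or many
#'   metabolites).
#' @return list of class `bm_relevance_summary` with `n_pairs_relevant`,
#'   `n_pairs_by_reliability`, `n_metabolites_by_category`.
#' @export
summarize_relevance <- function(calls) {
  rel <- calls[calls$category == "Tissue Relevant", , drop = FALSE]
  by_rel <- stats::setNames(
    as.integer(table(factor(rel$reliability, levels = c("High", "Medium", "Low")))),
    c("High", "Medium", "Low"))
  per_met <- tapply(seq_len(nrow(calls)), calls$metabolite, function(idx) {
    cat_i <- calls$category[idx]
    if (any(cat_i == "Tissue Relevant")) "Tissue Relevant"
    else if (any(calls$eligible[idx])) "Low tissue relevance"
    else "Unknown"
  })
  by_cat <- stats::setNames(
    as.integer(table(factor(per_met, levels = c("Tissue Relevant",
                                                "Low tissue relevance",
                                                "Unknown")))),
    c("Tissue Relevant", "Low tissue relevance", "Unknown"))
  structure(list(n_pairs_relevant = nrow(rel),
                 n_pairs_by_reliability = by_rel,
                 n_metabolites_by_category = by_cat),
            class = "bm_relevance_summary")
}

#' Tissue sets from relevance calls
#'
#' Builds the tissue -> metabolite mapping used by [tsa_enrichment()],
#' restricted by default to High/Medium-reliability pairs.
#'
#' @param calls a `bm_relevance_calls` table.
#' @param reliability reliability levels to keep.
#' @return named list: tissue -> character vector of metabolite keys.
#' @export
tissue_sets_from_calls <- function(calls, reliability = c("High", "Medium")) {
  keep <- calls$category == "Tissue Relevant" & calls$reliability %in% reliability
  sub <- calls[keep, , drop = FALSE]
  split(sub$metabolite, factor(sub$tissue, levels = unique(sub$tissue)))
}

#' Tissue enrichment of a metabolite list
#'
#' Runs the over-representation engine with tissues as terms: for each
#' tissue's relevant-metabolite set, a one-sided Fisher or binomial test of
#' overlap with the query against the background.
#'
#' @param query_metabolites character vector of metabolite keys.
#' @param tissue_sets named list tissue -> metabolite keys (see
#'   [tissue_sets_from_calls()]).
#' @param background character vector of background metabolites (defaults to
#'   the union of all tissue sets).
#' @param method,adjust as in [run_ora()].
#' @return a `bm_ora_result` with one row per tissue.
#' @export
tsa_enrichment <- function(query_metabolites, tissue_sets, background = NULL,
                           method = c("fisher", "binomial"),
                           adjust = c("BH", "bonferroni", "none")) {
  if (is.null(background)) background <- unique(unlist(tissue_sets))
  terms <- mapply(function(ts, mem) term_set(ts, mem, annotation_type = "Class",
                                             label = ts),
                  names(tissue_sets), tissue_sets, SIMPLIFY = FALSE)
  collection <- build_term_collection(terms, background, min_size = 1)
  run_ora(query_metabolites, collection, method = match.arg(method),
          adjust = match.arg(adjust))
}

#' Write relevance calls to TSV
#'
#' @param calls a `bm_relevance_calls` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_relevance_calls <- function(calls, path) {
  write_tsv_strict(as.data.frame(calls), path)
}
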