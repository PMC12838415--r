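# Non-redundant enrichment-term clustering: pairwise Cohen's kappa on binary
# membership vectors over the background, greedy representative selection at
# a fixed threshold, and cluster assignment.

#' Cohen's kappa between two term membership vectors
#'
#' Both terms are viewed as binary indicators over a common universe. With
#' observed agreement `O` (fraction of universe elements on which the two
#' indicators agree) and chance agreement `E = pA pB + (1-pA)(1-pB)`,
#' `kappa = (O - E) / (1 - E)`. When `E = 1` (both terms empty or both equal
#' to the whole universe) the indicators agree perfectly and 1 is returned
#' by convention.
#'
#' @param a,b character vectors of member keys (subsets of `universe`).
#' @param universe character vector; the common frame of reference.
#' @return kappa in `[-1, 1]`.
#' @export
kappa_score <- function(a, b, universe) {
  universe <- unique(universe)
  n <- length(universe)
  if (n == 0) stop("universe must be non-empty", call. = FALSE)
  in_a <- universe %in% a
  in_b <- universe %in% b
  o <- mean(in_a == in_b)
  pa <- mean(in_a); pb <- mean(in_b)
  e <- pa * pb + (1 - pa) * (1 - pb)
  if (e == 1) {
    bm_log("kappa: degenerate pair (chance agreement 1); returning 1")
    return(1)
  }
  (o - e) / (1 - e)
}

#' Pairwise kappa matrix of a term collection
#'
#' @param collection a `bm_term_collection`; kappa is computed over its
#'   universe (the enrichment background).
#' @return symmetric numeric matrix with term ids as dimnames.
#' @export
kappa_matrix <- function(collection) {
  members <- collection_members(collection)
  ids <- names(members)
  n <- length(ids)
  universe <- collection$universe
  ind <- vapply(members, function(m) universe %in% m,
                logical(length(universe)))
  km <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2) return(km)
  nu <- length(universe)
  p <- colMeans(ind)
  # O = P(both) + P(neither) = 2 P(both) + 1 - pi - pj, from one crossprod
  both <- crossprod(ind) / nu
  o <- 2 * both + 1 - outer(p, p, "+")
  e <- outer(p, p) + outer(1 - p, 1 - p)
  km[] <- ifelse(abs(1 - e) < .Machine$double.eps, 1, (o - e) / (1 - e))
  diag(km) <- 1
  km
}

#' Iterative selection of representative terms
#'
#' Terms are scanned from most to least significant; a term becomes a
#' representative iff its kappa with every previously accepted
#' representative is at most the threshold. The output therefore never
#' contains a representative pair with kappa above the threshold.
#'
#' @param ranked_terms character vector of term ids, most significant first
#'   (ties already broken, e.g. by term id).
#' @param kappa symmetric kappa matrix covering all listed terms.
#' @param threshold redundancy cutoff (default 0.3; comparisons are strict
#'   `>` on both sides of the algorithm).
#' @return character vector of representative term ids in acceptance order.
#' @export
select_representatives <- function(ranked_terms, kappa, threshold = 0.3) {
  missing <- setdiff(ranked_terms, rownames(kappa))
  if (length(missing) > 0) {
    stop(sprintf("kappa matrix lacks term(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  reps <- character()
  for (tid in ranked_terms) {
    if (length(reps) == 0 || all(kappa[tid, reps] <= threshold)) {
      reps <- c(reps, tid)
    }
  }
  reps
}

#' Assign terms to representative-led clusters
#'
#' Every non-representative joins the most significant (best-ranked)
#' representative with which its kappa exceeds the threshold; terms with no
#' such representative become singleton clusters (possible when the caller
#' ranks a filtered subset). Representatives map to themselves.
#'
#' @inheritParams select_representatives
#' @param representatives output of [select_representatives()].
#' @return list of class `bm_term_clustering`: `representatives`,
#'   `assignment` (named character vector term -> representative).
#' @export
assign_clusters <- function(ranked_terms, representatives, kappa,
                            threshold = 0.3) {
  assignment <- stats::setNames(character(length(ranked_terms)), ranked_terms)
  for (tid in ranked_terms) {
    if (tid %in% representatives) {
      assignment[[tid]] <- tid
    } else {
      linked <- representatives[kappa[tid, representatives] > threshold]
      if (length(linked) > 0) {
        assignment[[tid]] <- linked[[1]]  # representatives kept in rank order
      } else {
        assignment[[tid]] <- tid
        bm_log(sprintf("term %s links to no representative; kept as singleton",
                       tid))
      }
    }
  }
  # contract: representatives are mutually non-redundant
  if (length(representatives) > 1) {
    off <- kappa[representatives, representatives]
    diag(off) <- -Inf
    stopifnot(max(off) <= threshold)
  }
  structure(list(representatives = representatives, assignment = assignment),
            class = "bm_term_clustering")
}

#' Reduce an enrichment result to non-redundant term clusters
#'
#' Ranks terms by adjusted significance (ORA `p_adjusted` or MSEA `FDR`,
#' ties by term id), computes pairwise kappa over the collection universe,
#' selects representatives and assigns clusters.
#'
#' @param results a `bm_ora_result` or `bm_msea_result` (or any data frame
#'   with `term_id` and one of `p_adjusted`/`FDR`).
#' @param collection the `bm_term_collection` the results were computed on.
#' @param threshold kappa redundancy cutoff (default 0.3).
#' @return the input data frame with `representative_id` and `cluster_rank`
#'   columns appended (cluster_rank = 1 for representatives), carrying the
#'   `bm_term_clustering` as attribute `clustering`.
#' @export
reduce_terms <- function(results, collection, threshold = 0.3) {
  sig_col <- intersect(c("p_adjusted", "FDR"), names(results))[1]
  if (is.na(sig_col)) {
    stop("results must carry a p_adjusted or FDR column", call. = FALSE)
  }
  ord <- order(results[[sig_col]], results$term_id)
  ranked_terms <- results$term_id[ord]
  km <- kappa_matrix(collection)
  reps <- select_representatives(ranked_terms, km, threshold)
  clust <- assign_clusters(ranked_terms, reps, km, threshold)
  out <- results[ord, , drop = FALSE]
  out$representative_id <- unname(clust$assignment[out$term_id])
  grp <- tapply(seq_len(nrow(out)), out$representative_id, identity)
  out$cluster_rank <- NA_integer_
  for (g in grp) out$cluster_rank[g] <- seq_along(g)
  rownames(out) <- NULL
  attr(out, "clustering") <- clust
  out
}
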