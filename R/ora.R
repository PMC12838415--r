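# Over-representation analysis: hypergeometric (Fisher) or binomial upper
# tails per term, multiple-testing correction, tidy result table.

# Validate the 2x2 margin counts shared by both tests.
check_ora_counts <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop(sprintf("inconsistent overlap counts: k=%d n=%d K=%d N=%d", k, n, K, N),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided Fisher (hypergeometric) enrichment probability
#'
#' Upper-tail probability `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` term members in a sample of `n` from a
#' background of `N` containing `K` members. Identical to a one-sided
#' Fisher's exact test (alternative = greater) on the 2x2 overlap table.
#'
#' @param k observed overlap.
#' @param n input-list size (mapped to the background).
#' @param K term size within the background.
#' @param N background size.
#' @return the upper-tail probability.
#' @export
fisher_enrichment <- function(k, n, K, N) {
  check_ora_counts(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided binomial enrichment probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, K/N)`; the
#' sampling-with-replacement approximation to [fisher_enrichment()].
#'
#' @inheritParams fisher_enrichment
#' @return the upper-tail probability.
#' @export
binomial_enrichment <- function(k, n, K, N) {
  # with-replacement sampling: k may exceed K, unlike the hypergeometric
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N) {
    stop(sprintf("inconsistent overlap counts: k=%d n=%d K=%d N=%d", k, n, K, N),
         call. = FALSE)
  }
  stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the methods the
#' analyses use, with input validation. Output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method one of `BH` (Benjamini-Hochberg step-up), `bonferroni`,
#'   `none`.
#' @return adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Over-representation analysis of a metabolite list
#'
#' Tests each term in a collection for over-representation in the input
#' list. The input is deduplicated and intersected with the effective
#' background before testing; when a user-supplied background is given it is
#' first intersected with the collection universe, and term memberships are
#' re-intersected with it. One upper-tail test is run per term; raw
#' p-values are corrected across terms.
#'
#' @param input_ids character vector of metabolite keys (duplicates ignored).
#' @param collection a `bm_term_collection` (see [build_term_collection()]).
#' @param background optional character vector restricting the universe.
#' @param method `fisher` (hypergeometric) or `binomial`.
#' @param adjust multiple-testing method passed to [adjust_pvalues()].
#' @return data frame of class `bm_ora_result`, one row per term, sorted by
#'   raw p-value ascending (ties: larger overlap first, then term id), with
#'   columns `term_id`, `annotation_type`, `n_overlap`, `n_term`, `n_input`,
#'   `n_background`, `expected`, `fold_enrichment`, `p_raw`, `p_adjusted`
#'   and a `hits` list-column of overlapping keys.
#' @export
run_ora <- function(input_ids, collection, background = NULL,
                    method = c("fisher", "binomial"),
                    adjust = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "bm_term_collection"))
  eff_bg <- if (is.null(background)) {
    collection$universe
  } else {
    intersect(unique(as.character(background)), collection$universe)
  }
  if (length(eff_bg) == 0) stop("effective background is empty", call. = FALSE)

  input_ids <- unique(as.character(input_ids))
  mapped <- intersect(input_ids, eff_bg)
  unmapped <- setdiff(input_ids, eff_bg)
  if (length(unmapped) > 0) {
    bm_log(sprintf("%d of %d input IDs not in background: %s",
                   length(unmapped), length(input_ids),
                   paste(utils::head(unmapped, 10), collapse = ", ")),
           level = "warn")
  }
  if (length(mapped) == 0) {
    stop(sprintf("no input IDs map to the background; unmapped: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }

  N <- length(eff_bg)
  n <- length(mapped)
  test_fun <- if (method == "fisher") fisher_enrichment else binomial_enrichment

  rows <- lapply(collection$terms, function(tm) {
    members <- intersect(tm$members, eff_bg)
    hits <- intersect(mapped, members)
    K <- length(members)
    k <- length(hits)
    expected <- n * K / N
    data.frame(term_id = tm$term_id, annotation_type = tm$annotation_type,
               n_overlap = k, n_term = K, n_input = n, n_background = N,
               expected = expected,
               fold_enrichment = if (expected > 0) k / expected else NA_real_,
               p_raw = test_fun(k, n, K, N),
               hits = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adjusted <- adjust_pvalues(res$p_raw, adjust)
  ord <- order(res$p_raw, -res$n_overlap, res$term_id)
  res <- res[ord, c("term_id", "annotation_type", "n_overlap", "n_term",
                    "n_input", "n_background", "expected", "fold_enrichment",
                    "p_raw", "p_adjusted", "hits")]
  rownames(res) <- NULL
  class(res) <- c("bm_ora_result", "data.frame")
  res
}

#' Write an ORA (or tissue-enrichment) result table to TSV
#'
#' The `hits` list-column is flattened to a pipe-delimited string.
#'
#' @param res a `bm_ora_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ora <- function(res, path) {
  out <- as.data.frame(res)
  out$hits <- vapply(out$hits, paste, character(1), collapse = "|")
  write_tsv_strict(out, path)
}
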