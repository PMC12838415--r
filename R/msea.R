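# Pre-ranked metabolite set enrichment analysis: weighted running-sum
# enrichment score, set-label permutation null, normalized scores and
# GSEA-style FDR.

#' Construct a ranked metabolite list
#'
#' Scores are sorted in decreasing order; ties are broken by metabolite key
#' ascending so that ranking is deterministic.
#'
#' @param hub_ids character vector of unique metabolite keys.
#' @param scores numeric vector of the same length (fold changes,
#'   correlations, model coefficients, ...).
#' @return data frame of class `bm_ranked_list` with columns `hub_id`,
#'   `score`, sorted.
#' @export
ranked_list <- function(hub_ids, scores) {
  hub_ids <- as.character(hub_ids)
  if (anyDuplicated(hub_ids)) {
    stop("ranked list metabolite keys must be unique", call. = FALSE)
  }
  if (length(hub_ids) != length(scores)) {
    stop("hub_ids and scores must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(-scores, hub_ids)
  out <- data.frame(hub_id = hub_ids[ord], score = as.numeric(scores[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("bm_ranked_list", "data.frame")
  out
}

#' Read a ranked list from a strictly two-column TSV
#'
#' @param path TSV with columns `hub_id` (or `metabolite_id`) and `score`.
#' @return a `bm_ranked_list`.
#' @export
read_ranked_list <- function(path) {
  df <- read_tsv_strict(path, what = "ranked list")
  if (ncol(df) != 2) {
    stop(sprintf("ranked list %s must have exactly two columns (id, score)",
                 path), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(score))) {
    stop(sprintf("ranked list %s: non-numeric score at line(s) %s", path,
                 paste(which(is.na(score)) + 1L, collapse = ", ")),
         call. = FALSE)
  }
  ranked_list(df[[1]], score)
}

# Running-sum core shared by the observed statistic and the permutation
# null. `w` is |score|^p over the whole list, `is_hit` a logical vector.
es_running_sum <- function(w, is_hit, N) {
  n_hit <- sum(is_hit)
  sw <- sum(w[is_hit])
  step <- numeric(N)
  if (sw > 0) {
    step[is_hit] <- w[is_hit] / sw
  } else {
    # all hit scores are exactly zero: fall back to equal hit increments
    step[is_hit] <- 1 / n_hit
  }
  step[!is_hit] <- -1 / (N - n_hit)
  cumsum(step)
}

#' Running-sum enrichment score of a metabolite set
#'
#' Walks the ranked list top to bottom: at each member ("hit") the running
#' sum rises by that metabolite's weight `|score|^p` normalized over the
#' member weights, at each non-member it falls by `1/(N - N_hit)`. The
#' enrichment score is the signed maximum deviation from zero; the leading
#' edge is the set of members at or before the extremum (positive ES) or at
#' or after it (negative ES).
#'
#' @param ranked a `bm_ranked_list`.
#' @param members character vector of member keys.
#' @param p weight exponent (>= 0); `p = 0` gives the classic unweighted
#'   Kolmogorov-Smirnov-like statistic, `p = 1` the weighted default.
#' @return list with `ES` (in `[-1, 1]`), `running_sum` (length-N numeric)
#'   and `leading_edge` (character vector).
#' @export
enrichment_score <- function(ranked, members, p = 1) {
  stopifnot(p >= 0)
  N <- nrow(ranked)
  is_hit <- ranked$hub_id %in% members
  n_hit <- sum(is_hit)
  if (n_hit == 0 || n_hit == N) {
    stop("member set must be a non-empty proper subset of the ranked list",
         call. = FALSE)
  }
  w <- abs(ranked$score)^p
  run <- es_running_sum(w, is_hit, N)
  i_ext <- which.max(abs(run))
  es <- run[i_ext]
  leading <- if (es >= 0) {
    ranked$hub_id[seq_len(i_ext)][is_hit[seq_len(i_ext)]]
  } else {
    idx <- i_ext:N
    ranked$hub_id[idx][is_hit[idx]]
  }
  list(ES = es, running_sum = run, leading_edge = leading)
}

#' Permutation null distribution of the enrichment score
#'
#' Metabolite-label permutation: for each permutation a uniform random set of
#' `set_size` positions in the ranked list is treated as the member set and
#' its enrichment score recorded. Deterministic given `seed`.
#'
#' @param ranked a `bm_ranked_list`.
#' @param set_size size of the permuted sets; must be `< nrow(ranked)`.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param p weight exponent as in [enrichment_score()].
#' @return numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000, seed = 0, p = 1) {
  N <- nrow(ranked)
  if (set_size < 1 || set_size >= N) {
    stop(sprintf("set_size must be in [1, %d]", N - 1), call. = FALSE)
  }
  stopifnot(n_perm >= 1)
  w <- abs(ranked$score)^p
  null_es <- numeric(n_perm)
  rng <- local({
    set.seed(seed)
    function(n, k) sample.int(n, k)
  })
  is_hit <- logical(N)
  for (b in seq_len(n_perm)) {
    idx <- rng(N, set_size)
    is_hit[] <- FALSE
    is_hit[idx] <- TRUE
    run <- es_running_sum(w, is_hit, N)
    null_es[b] <- run[which.max(abs(run))]
  }
  null_es
}

#' MSEA configuration
#'
#' @param weight_exponent running-sum weight exponent `p` (default 1).
#' @param n_permutations permutation count for the null (default 1000).
#' @param seed integer RNG seed (default 0).
#' @param min_set_size,max_set_size retained term-size range after
#'   intersection with the ranked universe.
#' @return list of class `bm_msea_config`.
#' @export
msea_config <- function(weight_exponent = 1, n_permutations = 1000, seed = 0,
                        min_set_size = 5, max_set_size = 500) {
  stopifnot(weight_exponent >= 0, n_permutations >= 1,
            min_set_size <= max_set_size, min_set_size >= 1)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 min_set_size = min_set_size, max_set_size = max_set_size),
            class = "bm_msea_config")
}

#' Metabolite set enrichment analysis over a ranked list
#'
#' For every term surviving the size filter the observed enrichment score is
#' computed, a permutation null of matching set size is drawn
#' (metabolite-label permutation; one null per distinct set size, shared
#' across terms of that size), and three quantities are derived: a smoothed
#' nominal p-value (fraction of same-sign null scores at least as extreme,
#' with a +1 smoothing so p is never exactly zero), the normalized score
#' `NES = ES / mean(|null ES| of the same sign)`, and a GSEA-style FDR
#' q-value comparing the observed NES distribution with the pooled permuted
#' NES distribution, clipped to `[0, 1]`.
#'
#' @param ranked a `bm_ranked_list`.
#' @param collection a `bm_term_collection`.
#' @param config a [msea_config()].
#' @return data frame of class `bm_msea_result`, one row per tested term,
#'   sorted by FDR ascending then `|NES|` descending, with a `leading_edge`
#'   list-column.
#' @export
run_msea <- function(ranked, collection, config = msea_config()) {
  stopifnot(inherits(ranked, "bm_ranked_list"),
            inherits(collection, "bm_term_collection"))
  N <- nrow(ranked)
  universe <- ranked$hub_id

  sets <- list()
  for (tm in collection$terms) {
    mem <- intersect(tm$members, universe)
    sz <- length(mem)
    if (sz == 0) {
      bm_log(sprintf("term %s lies outside the ranked universe; excluded",
                     tm$term_id))
      next
    }
    if (sz < config$min_set_size || sz > config$max_set_size || sz >= N) next
    sets[[tm$term_id]] <- mem
  }
  if (length(sets) == 0) {
    stop("no term survives the size filter against the ranked list",
         call. = FALSE)
  }

  # One permutation null per distinct set size, seeded independently of the
  # term order so that adding a term never perturbs another term's null.
  sizes <- sort(unique(vapply(sets, length, integer(1))))
  nulls <- lapply(sizes, function(sz) {
    permutation_null(ranked, sz, n_perm = config$n_permutations,
                     seed = derive_seed(config$seed, sz),
                     p = config$weight_exponent)
  })
  names(nulls) <- as.character(sizes)

  norm_null <- function(null_es) {
    pos_mean <- mean(null_es[null_es >= 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    out <- null_es
    out[null_es >= 0] <- null_es[null_es >= 0] / pos_mean
    out[null_es < 0] <- null_es[null_es < 0] / neg_mean
    out
  }
  pooled_null_nes <- unlist(lapply(nulls, norm_null), use.names = FALSE)
  pooled_null_nes <- pooled_null_nes[is.finite(pooled_null_nes)]

  rows <- lapply(names(sets), function(tid) {
    mem <- sets[[tid]]
    es_obj <- enrichment_score(ranked, mem, p = config$weight_exponent)
    es <- es_obj$ES
    null_es <- nulls[[as.character(length(mem))]]
    same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p_nom <- (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
    denom <- mean(abs(same_sign))
    nes <- if (length(same_sign) == 0 || denom == 0) {
      bm_log(sprintf("term %s: no same-sign permutation scores; NES undefined",
                     tid), level = "warn")
      NA_real_
    } else {
      es / denom
    }
    data.frame(term_id = tid, size = length(mem), ES = es, NES = nes,
               p_nominal = min(p_nom, 1),
               leading_edge = I(list(es_obj$leading_edge)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  # GSEA-style FDR: tail fraction in the pooled null NES relative to the
  # tail fraction in the observed NES, per sign.
  res$FDR <- vapply(seq_len(nrow(res)), function(i) {
    nes <- res$NES[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      null_tail <- sum(pooled_null_nes >= nes) / max(1, sum(pooled_null_nes >= 0))
      obs_tail <- sum(res$NES >= nes, na.rm = TRUE) /
        max(1, sum(res$NES >= 0, na.rm = TRUE))
    } else {
      null_tail <- sum(pooled_null_nes <= nes) / max(1, sum(pooled_null_nes < 0))
      obs_tail <- sum(res$NES <= nes, na.rm = TRUE) /
        max(1, sum(res$NES < 0, na.rm = TRUE))
    }
    min(1, max(0, null_tail / obs_tail))
  }, numeric(1))

  ord <- order(res$FDR, -abs(res$NES), res$term_id)
  res <- res[ord, c("term_id", "size", "ES", "NES", "p_nominal", "FDR",
                    "leading_edge")]
  rownames(res) <- NULL
  class(res) <- c("bm_msea_result", "data.frame")
  res
}

#' Write an MSEA result table to TSV
#'
#' @param res a `bm_msea_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_msea <- function(res, path) {
  out <- as.data.frame(res)
  out$leading_edge <- vapply(out$leading_edge, paste, character(1),
                             collapse = "|")
  write_tsv_strict(out, path)
}
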