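# Shared fixtures and independent brute-force oracles used across the suite.

# Small hand-built catalog with known synonyms and identifiers.
tiny_catalog <- function() {
  metabolite_catalog(
    hub_id = c("HUB1", "HUB2", "HUB3", "HUB4"),
    name = c("D-Glucose", "L-Lactic acid", "D-Lactic acid", "ATP"),
    category = c("Carbohydrate", "Energy", "Energy", "Nucleotide"),
    synonyms = c("Glucose|Dextrose", "lactate|L-lactate", "Lactate",
                 "Adenosine triphosphate"),
    identifiers = list(HMDB = c("HMDB0000122", "HMDB0000190", "", "HMDB0000538"),
                       KEGG = c("C00031", "C00186", "C00256", "C00002"))
  )
}

# Deterministic expression table: `elevated` marks given (protein, tissue)
# cells; their ntpm is multiplied by `fold`.
toy_expression <- function(proteins, tissues, base = 10, fold = 10,
                           elevated_cells = NULL) {
  ntpm <- matrix(base, length(proteins), length(tissues),
                 dimnames = list(proteins, tissues))
  elev <- matrix(FALSE, length(proteins), length(tissues),
                 dimnames = list(proteins, tissues))
  if (!is.null(elevated_cells)) {
    for (cell in elevated_cells) {
      ntpm[cell[1], cell[2]] <- ntpm[cell[1], cell[2]] * fold
      elev[cell[1], cell[2]] <- TRUE
    }
  }
  tissue_expression(ntpm, elev)
}

# Independent running-sum oracle: explicit element-by-element walk, no
# vectorization shared with the implementation.
es_bruteforce <- function(ids, scores, members, p) {
  N <- length(ids)
  is_hit <- ids %in% members
  sw <- sum(abs(scores[is_hit])^p)
  phit <- 0; pmiss <- 0
  run <- numeric(N)
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      phit <- phit + if (sw > 0) abs(scores[i])^p / sw else 1 / sum(is_hit)
    } else {
      pmiss <- pmiss + 1 / (N - sum(is_hit))
    }
    run[i] <- phit - pmiss
  }
  run[which.max(abs(run))]
}

# Upper hypergeometric tail by direct summation of binomial coefficients.
hyper_tail_bruteforce <- function(k, n, K, N) {
  xs <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Cohen's kappa recomputed from the literal 2x2 agreement table.
kappa_bruteforce <- function(a, b, universe) {
  x <- factor(universe %in% a, levels = c(FALSE, TRUE))
  y <- factor(universe %in% b, levels = c(FALSE, TRUE))
  tab <- table(x, y) / length(universe)
  o <- sum(diag(tab))
  e <- sum(rowSums(tab) * colSums(tab))
  if (e == 1) return(1)
  (o - e) / (1 - e)
}
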