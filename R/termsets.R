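# Annotation term sets: GMT-style I/O and filtered term collections used as
# the testing frame for enrichment analyses.

ANNOTATION_TYPES <- c("Class", "Pathway", "Disease", "Drug")

#' Construct an annotation term set
#'
#' @param term_id unique term identifier.
#' @param members character vector of metabolite keys; duplicates are dropped.
#' @param annotation_type one of `Class`, `Pathway`, `Disease`, `Drug`.
#' @param label human-readable label (defaults to `term_id`).
#' @param source free-text provenance tag.
#' @return list of class `bm_term`.
#' @export
term_set <- function(term_id, members, annotation_type = "Pathway",
                     label = term_id, source = "") {
  if (!annotation_type %in% ANNOTATION_TYPES) {
    stop(sprintf("annotation_type must be one of: %s",
                 paste(ANNOTATION_TYPES, collapse = ", ")), call. = FALSE)
  }
  structure(list(term_id = as.character(term_id),
                 label = as.character(label),
                 annotation_type = annotation_type,
                 source = as.character(source),
                 members = unique(as.character(members))),
            class = "bm_term")
}

#' Build a term collection over a background universe
#'
#' Term memberships are first intersected with the universe; terms left with
#' fewer than `min_size` members are then dropped. Five is the conventional
#' minimum for a term to be statistically testable.
#'
#' @param terms list of [term_set()] objects.
#' @param universe character vector of metabolite keys forming the
#'   background.
#' @param min_size minimum retained term size (default 5).
#' @return list of class `bm_term_collection` with elements `terms` (named
#'   list) and `universe`.
#' @export
build_term_collection <- function(terms, universe, min_size = 5) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty", call. = FALSE)
  stopifnot(min_size >= 1)
  kept <- list()
  for (tm in terms) {
    tm$members <- intersect(tm$members, universe)
    if (length(tm$members) >= min_size) kept[[tm$term_id]] <- tm
  }
  bm_log(sprintf("term collection: kept %d of %d terms (min_size=%d, universe=%d)",
                 length(kept), length(terms), min_size, length(universe)))
  structure(list(terms = kept, universe = universe),
            class = "bm_term_collection")
}

#' Read term sets from a GMT-style file
#'
#' One term per line: `term_id <TAB> "type=<Class|Pathway|Disease|Drug>;label=<text>"
#' <TAB> member <TAB> member ...`. Malformed lines are rejected with their
#' line numbers.
#'
#' @param path path to the GMT file.
#' @return list of [term_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  terms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT %s line %d: expected at least 3 tab-separated fields",
                   path, i), call. = FALSE)
    }
    desc <- fields[[2]]
    type <- sub(".*type=([^;]+).*", "\\1", desc)
    label <- if (grepl("label=", desc, fixed = TRUE)) {
      sub(".*label=([^;]*).*", "\\1", desc)
    } else {
      fields[[1]]
    }
    if (!type %in% ANNOTATION_TYPES) {
      stop(sprintf("GMT %s line %d: missing or invalid 'type=' field (valid: %s)",
                   path, i, paste(ANNOTATION_TYPES, collapse = ", ")), call. = FALSE)
    }
    terms[[i]] <- term_set(fields[[1]], fields[-(1:2)],
                           annotation_type = type, label = label)
  }
  terms
}

#' Write term sets to a GMT-style file
#'
#' @param terms list of [term_set()] objects or a `bm_term_collection`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(terms, path) {
  if (inherits(terms, "bm_term_collection")) terms <- terms$terms
  lines <- vapply(terms, function(tm) {
    paste(c(tm$term_id,
            sprintf("type=%s;label=%s", tm$annotation_type, tm$label),
            tm$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Named list of member vectors for a collection (internal convenience).
collection_members <- function(collection) {
  lapply(collection$terms, `[[`, "members")
}
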