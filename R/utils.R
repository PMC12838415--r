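# Shared helpers: rounding, logging, TSV I/O conventions.

#' Round half-up
#'
#' Decimal rounding where ties go away from zero, matching how percentages
#' are conventionally printed (e.g. 58.735 -> 58.74 at two decimals). Base
#' `round()` uses banker's rounding and is not suitable for reporting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Package-level logging: plain messages, suppressible via option.
bm_log <- function(..., level = "info") {
  verbosity <- getOption("bloodmet.log_level", "info")
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[verbosity]] && verbosity != "quiet") {
    message(sprintf("[%s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

# Strict TSV conventions: header row, tab-separated, UTF-8, "." decimal,
# no quoting surprises. Used by every reader/writer in the package.
read_tsv_strict <- function(path, required_cols = NULL, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", na.strings = NULL)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0) {
      stop(sprintf("%s file %s is missing required column(s): %s",
                   what, path, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Derive a reproducible substream seed from a base seed and a fixed offset,
# kept inside the 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000 + offset) %% .Machine$integer.max)
}
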