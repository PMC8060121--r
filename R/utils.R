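# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV table with '#' comment lines
#'
#' All input tables in this package are UTF-8 tab-separated files with a
#' header row; lines starting with '#' are ignored.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame with character columns (no factor conversion).
#' @keywords internal
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# Write a data.frame as a plain TSV (no quoting, no row names); the inverse
# of read_tsv_checked for round-tripping pipeline artefacts.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Stop unless `cond`; message built from ... like stop().
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# Normalize gene identifiers: uppercase, trimmed. No mapping service is
# bundled, so this is the only identifier harmonisation performed.
normalize_gene <- function(x) toupper(trimws(x))
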