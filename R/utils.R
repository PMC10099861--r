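# Condition helpers: every user-facing error carries a holoscope_* class so the
# pipeline runner can map failures to exit codes.

hs_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "holoscope_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

format_error <- function(msg, ...) hs_error(msg, "holoscope_format_error", ...)
validation_error <- function(msg, ...) hs_error(msg, "holoscope_validation_error", ...)
dependency_error <- function(msg, ...) hs_error(msg, "holoscope_dependency_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-delimited table
#'
#' Thin wrapper around [utils::read.delim()] enforcing the package's TSV
#' conventions (UTF-8, header row, no factor coercion, no name mangling).
#'
#' @param path File path.
#' @param required_cols Character vector of column names that must be present.
#' @return A `data.frame`.
#' @keywords internal
read_tsv_checked <- function(path, required_cols = NULL) {
  if (!file.exists(path)) {
    format_error(sprintf("file not found: %s", path))
  }
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing)) {
      format_error(sprintf("%s: missing required column(s): %s",
                           path, paste(missing, collapse = ", ")))
    }
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# Matrix -> TSV with an explicit id column; inverse of read_matrix_tsv().
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path, id_col = NULL) {
  df <- read_tsv_checked(path)
  if (is.null(id_col)) id_col <- names(df)[1]
  mat <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(mat) <- df[[id_col]]
  mat
}
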