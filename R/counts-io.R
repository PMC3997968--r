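#' Read a miRNA count table
#'
#' Reads a TSV/CSV table with miRNA identifiers in the first column (or in a
#' `#miRNA` column, the dialect written by common small-RNA quantifiers) and
#' one column of raw read counts per sample. Metadata columns named
#' `precursor`, `total` or `read_count`, and derived columns whose name
#' contains `(norm)`, are dropped. Numbers printed with a European decimal
#' comma (`"215390,119"`) are handled: with `decimal_comma = "auto"` the
#' reader switches the decimal separator when it sees comma-in-number cells
#' in a non-comma-separated file.
#'
#' @param path path to the table.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma vs
#'   semicolon from the header line.
#' @param decimal_comma `"auto"` (default), `TRUE` or `FALSE`.
#' @param duplicates what to do with repeated miRNA ids (e.g. one row per
#'   precursor): `"sum"` (default, with a message), `"first"` or `"error"`.
#' @return numeric matrix of counts, miRNAs in rows, samples in columns.
#' @export
read_count_table <- function(path, sep = NULL, decimal_comma = "auto",
                             duplicates = c("sum", "first", "error")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) abort("count table not found: %s", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", header)) "\t"
           else if (grepl(";", header)) ";"
           else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) abort("count table needs an id column and >= 1 sample column")

  cn <- names(df)
  id_col <- if ("#miRNA" %in% cn) "#miRNA" else cn[1L]
  ids <- trimws(df[[id_col]])
  drop <- unique(c(id_col,
                   cn[tolower(cn) %in% c("precursor", "total", "read_count")],
                   cn[grepl("(norm)", cn, fixed = TRUE)]))
  value_cols <- setdiff(cn, drop)
  if (!length(value_cols)) abort("no sample columns found in %s", path)

  cells <- unlist(df[value_cols], use.names = FALSE)
  use_comma <- if (identical(decimal_comma, "auto")) {
    sep != "," && any(grepl("^-?[0-9]+,[0-9]+$", cells))
  } else isTRUE(decimal_comma)

  mat <- vapply(df[value_cols], parse_decimal, numeric(nrow(df)),
                decimal_comma = use_comma)
  mat <- matrix(mat, nrow = nrow(df), dimnames = list(ids, value_cols))
  if (anyNA(mat)) abort("non-numeric count cells in %s", path)

  if (anyDuplicated(ids)) {
    if (duplicates == "error")
      abort("duplicate miRNA ids in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (duplicates == "sum") {
      message(sprintf("summing counts over %d duplicated miRNA id(s)",
                      length(unique(ids[duplicated(ids)]))))
      mat <- rowsum(mat, group = ids, reorder = FALSE)
    } else {
      mat <- mat[!duplicated(ids), , drop = FALSE]
    }
  }
  as_count_matrix(mat)
}

#' Write a stability report as TSV
#'
#' One row per miRNA: id, percent variation, abundance flag, passed flag.
#'
#' @param report a `"stability_report"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stability_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stability report or condition intersection as JSON
#'
#' The JSON carries the full report including thresholds, so a run can be
#' audited and reproduced.
#'
#' @param x a `"stability_report"` or `"condition_intersection"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(x, path) {
  obj <- unclass(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
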