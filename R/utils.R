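#' @keywords internal
"_PACKAGE"

# stop() without the call, sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @keywords internal
geo_mean <- function(x) {
  if (any(x <= 0)) abort("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Coerce a count table (matrix or data.frame with an id column already as
# rownames) to a validated numeric matrix of raw counts.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("counts must be a numeric matrix (miRNAs in rows, samples in columns)")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    abort("count matrix needs at least one miRNA and one sample")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("mirna_%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    abort("duplicate miRNA identifiers: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort("duplicate sample identifiers: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts))) abort("counts contain missing or non-finite values")
  if (any(counts < 0)) abort("counts must be nonnegative")
  counts
}

# Parse numbers that may use a decimal comma ("215390,119").
parse_decimal <- function(x, decimal_comma = FALSE) {
  x <- trimws(as.character(x))
  if (decimal_comma) x <- sub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}
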