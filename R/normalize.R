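#' Normalize a raw miRNA count matrix to a common library size
#'
#' Each sample's counts are divided by that sample's total miRNA reads and
#' multiplied by the mean total over all samples, so every normalized column
#' sums to the same value (the mean raw library size). A pseudocount is then
#' added and the result log2-transformed; the pseudocount enters only the log
#' layer, never the linear layer used by abundance filters.
#'
#' @param counts numeric matrix of raw read counts, miRNAs in rows and
#'   samples (barcodes) in columns, or a data.frame coercible to one. Row and
#'   column names are the miRNA and sample identifiers.
#' @param pseudocount nonnegative constant added to the normalized linear
#'   values before log2 transformation. Default 10.
#' @return An object of class `"mirna_norm"`: a list with elements
#'   \describe{
#'     \item{linear}{normalized reads, same dimensions as `counts`;
#'       every column sums to `mean(colSums(counts))`.}
#'     \item{log2}{`log2(linear + pseudocount)`.}
#'     \item{pseudocount}{the pseudocount used.}
#'     \item{raw_totals}{per-sample raw totals.}
#'   }
#' @examples
#' counts <- matrix(c(100, 900, 300, 700), nrow = 2,
#'                  dimnames = list(c("mir-a", "mir-b"), c("s1", "s2")))
#' norm <- normalize_counts(counts)
#' colSums(norm$linear)  # equal library sizes
#' @export
normalize_counts <- function(counts, pseudocount = 10) {
  counts <- as_count_matrix(counts)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    abort("pseudocount must be a single nonnegative number")
  totals <- colSums(counts)
  if (any(totals == 0))
    abort("sample(s) with zero total reads cannot be normalized: %s",
          paste(colnames(counts)[totals == 0], collapse = ", "))
  linear <- sweep(counts, 2L, totals, "/") * mean(totals)
  structure(
    list(linear = linear,
         log2 = log2(linear + pseudocount),
         pseudocount = pseudocount,
         raw_totals = totals),
    class = "mirna_norm")
}

#' @export
print.mirna_norm <- function(x, ...) {
  cat(sprintf("Normalized miRNA counts: %d miRNAs x %d samples\n",
              nrow(x$linear), ncol(x$linear)))
  cat(sprintf("  common library size: %.1f reads (mean of raw totals)\n",
              mean(x$raw_totals)))
  cat(sprintf("  pseudocount for log2 layer: %g\n", x$pseudocount))
  invisible(x)
}
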