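#' Read a long-format Cq panel
#'
#' Expects columns `gene`, `sample`, `replicate`, `cq` (case-insensitive;
#' `mirna` is accepted for `gene`, `bio_sample` for `sample`). The panel
#' holds one quantification-cycle value per technical replicate of each
#' (gene, biological sample) combination.
#'
#' @param x path to a CSV/TSV file, or a data.frame.
#' @return data.frame with columns gene, sample, replicate, cq.
#' @export
read_cq_panel <- function(x) {
  df <- read_long_table(x)
  df <- rename_first(df, gene = c("gene", "mirna"),
                     sample = c("sample", "bio_sample", "biological_sample"),
                     replicate = c("replicate", "rep", "technical_replicate"),
                     cq = c("cq", "ct"))
  df$cq <- as.numeric(df$cq)
  if (any(!is.finite(df$cq))) abort("Cq panel contains non-finite Cq values")
  df[c("gene", "sample", "replicate", "cq")]
}

#' Read a dilution-series table
#'
#' Expects columns `gene`, `dilution_factor` (or `dilution`) and `cq`.
#' Replicate rows per dilution are allowed and all enter the efficiency fit.
#'
#' @param x path to a CSV/TSV file, or a data.frame.
#' @return data.frame with columns gene, dilution_factor, cq.
#' @export
read_dilution_series <- function(x) {
  df <- read_long_table(x)
  df <- rename_first(df, gene = c("gene", "mirna"),
                     dilution_factor = c("dilution_factor", "dilution"),
                     cq = c("cq", "ct"))
  df$dilution_factor <- as.numeric(df$dilution_factor)
  df$cq <- as.numeric(df$cq)
  if (any(!is.finite(df$cq))) abort("dilution series contains non-finite Cq values")
  if (any(df$dilution_factor <= 0)) abort("dilution factors must be positive")
  df[c("gene", "dilution_factor", "cq")]
}

read_long_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!file.exists(x)) abort("file not found: %s", x)
  header <- readLines(x, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

rename_first <- function(df, ...) {
  spec <- list(...)
  low <- tolower(names(df))
  for (target in names(spec)) {
    hit <- which(low %in% spec[[target]])
    if (!length(hit)) abort("required column '%s' not found", target)
    names(df)[hit[1L]] <- target
  }
  df
}

#' Average technical replicates of a Cq panel
#'
#' Technical replicates are averaged on the Cq scale (before any
#' transformation to quantities); the replicate spread is retained as a QC
#' column. Missing (gene, sample) combinations are an error, not silently
#' dropped: a panel is expected to cover its full design grid.
#'
#' @param panel data.frame from [read_cq_panel()].
#' @return data.frame with columns gene, sample, cq (replicate mean),
#'   cq_sd (replicate standard deviation, NA for singletons), n_reps.
#' @export
collapse_replicates <- function(panel) {
  panel <- read_cq_panel(panel)
  genes <- unique(panel$gene)
  samples <- unique(panel$sample)
  grid <- expand.grid(gene = genes, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(panel$gene, panel$sample, sep = "\r")
  want <- paste(grid$gene, grid$sample, sep = "\r")
  gaps <- !(want %in% have)
  if (any(gaps))
    abort("Cq panel is missing %d (gene, sample) combination(s): %s",
          sum(gaps),
          paste(sprintf("(%s, %s)", grid$gene[gaps], grid$sample[gaps]),
                collapse = ", "))
  agg <- stats::aggregate(cq ~ gene + sample, data = panel,
                   FUN = function(v) c(mean = mean(v),
                                       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                                       n = length(v)))
  out <- data.frame(gene = agg$gene, sample = agg$sample,
                    cq = agg$cq[, "mean"], cq_sd = agg$cq[, "sd"],
                    n_reps = as.integer(agg$cq[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(match(out$gene, genes), match(out$sample, samples)), , drop = FALSE]
}

# gene x sample matrix of replicate-mean Cq values
cq_matrix <- function(collapsed) {
  genes <- unique(collapsed$gene)
  samples <- unique(collapsed$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(collapsed$gene, genes), match(collapsed$sample, samples))] <-
    collapsed$cq
  m
}

#' Fit primer amplification efficiency from a dilution series
#'
#' Ordinary least squares of Cq against log10(dilution factor); Cq rises
#' with dilution, so the slope is positive (about +3.32 per 10-fold dilution
#' for perfect doubling). Percent efficiency follows
#' `E\% = (10^(1/slope) - 1) * 100`.
#'
#' @param series data.frame with columns `dilution_factor` and `cq`
#'   (a `gene` column is allowed; it must then hold a single gene —
#'   use [efficiency_table()] for multi-gene input). Replicates per
#'   dilution enter the regression as individual points.
#' @param gene label stored in the fit; taken from the data if present.
#' @return Object of class `"efficiency_fit"`: list with `gene`, `slope`
#'   (Cq per log10 dilution), `efficiency_pct`, `r_squared` and the
#'   underlying `lm` fit.
#' @examples
#' s <- data.frame(dilution_factor = 10^(0:4),
#'                 cq = 20 + (0:4) * 1 / log10(2))
#' fit_efficiency(s)  # 100% efficient, R^2 = 1
#' @export
fit_efficiency <- function(series, gene = NULL) {
  if (!is.data.frame(series)) abort("series must be a data.frame")
  if ("gene" %in% names(series)) {
    g <- unique(series$gene)
    if (length(g) > 1L)
      abort("fit_efficiency takes one gene at a time (got %d); see efficiency_table",
            length(g))
    gene <- gene %||% g
  }
  if (!all(c("dilution_factor", "cq") %in% names(series)))
    abort("series needs columns dilution_factor and cq")
  if (any(series$dilution_factor <= 0)) abort("dilution factors must be positive")
  if (any(!is.finite(series$cq))) abort("non-finite Cq in dilution series")
  if (length(unique(series$dilution_factor)) < 3L)
    abort("need at least 3 distinct dilution factors (got %d)",
          length(unique(series$dilution_factor)))

  dat <- data.frame(log_dil = log10(series$dilution_factor), cq = series$cq)
  fit <- stats::lm(cq ~ log_dil, data = dat)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) abort("singular or flat efficiency fit")
  if (slope < 0)
    warn("negative slope (%.3f): Cq should rise with dilution; check the dilution_factor convention",
         slope)
  # computed directly (1 - SSE/SST); summary.lm warns on noiseless series
  r2 <- 1 - sum(stats::residuals(fit) ^ 2) / sum((dat$cq - mean(dat$cq)) ^ 2)
  structure(
    list(gene = gene %||% "gene", slope = slope,
         efficiency_pct = (10 ^ (1 / slope) - 1) * 100,
         r_squared = r2, fit = fit),
    class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Amplification efficiency fit for %s\n", x$gene))
  cat(sprintf("  slope: %.*g Cq per log10 dilution\n", digits, x$slope))
  cat(sprintf("  efficiency: %.*g%%   R^2: %.*g\n",
              digits, x$efficiency_pct, digits, x$r_squared))
  invisible(x)
}

#' @export
coef.efficiency_fit <- function(object, ...) stats::coef(object$fit)

#' @export
predict.efficiency_fit <- function(object, dilution_factor, ...) {
  unname(stats::predict(object$fit,
                        newdata = data.frame(log_dil = log10(dilution_factor))))
}

#' Efficiency table for a multi-gene dilution data set
#'
#' Fits [fit_efficiency()] per gene and returns the standard reporting table
#' (gene, slope, percent efficiency, R squared).
#'
#' @param dilutions data.frame with columns gene, dilution_factor, cq
#'   (or a file path readable by [read_dilution_series()]).
#' @return data.frame with one row per gene; attribute `"fits"` holds the
#'   named list of `"efficiency_fit"` objects.
#' @export
efficiency_table <- function(dilutions) {
  dilutions <- read_dilution_series(dilutions)
  fits <- lapply(split(dilutions, dilutions$gene), fit_efficiency)
  fits <- fits[unique(dilutions$gene)]
  out <- data.frame(
    gene = names(fits),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    efficiency_pct = vapply(fits, `[[`, numeric(1), "efficiency_pct"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Efficiency-corrected relative quantities from mean Cq values
#'
#' Converts replicate-mean Cq values into relative quantities
#' `Q = (1 + E/100)^(Cq_ref - Cq)`, with a per-gene reference Cq so that
#' quantities are comparable across samples within each gene. With the
#' default `ref = "min"` the reference is the gene's lowest mean Cq, so the
#' most abundant sample has quantity exactly 1 and all others are <= 1.
#' Every downstream geNorm statistic is invariant to this per-gene scaling.
#'
#' @param mean_cq data.frame from [collapse_replicates()] (columns gene,
#'   sample, cq) or a gene x sample numeric matrix of mean Cq values.
#' @param efficiencies named numeric vector of percent efficiencies, an
#'   [efficiency_table()] data.frame, or a list of `"efficiency_fit"`s.
#' @param ref `"min"` (default) or `"mean"` reference Cq per gene.
#' @return gene x sample matrix of positive relative quantities with
#'   attribute `"ref_cq"` (named per-gene reference Cq).
#' @export
relative_quantities <- function(mean_cq, efficiencies, ref = c("min", "mean")) {
  ref <- match.arg(ref)
  cqm <- if (is.matrix(mean_cq)) mean_cq else cq_matrix(mean_cq)
  if (any(!is.finite(cqm))) abort("non-finite mean Cq values")
  eff <- extract_efficiencies(efficiencies)
  missing <- setdiff(rownames(cqm), names(eff))
  if (length(missing))
    abort("no efficiency for gene(s): %s", paste(missing, collapse = ", "))
  eff <- eff[rownames(cqm)]
  if (any(eff <= -100)) abort("efficiencies must exceed -100%%")
  ref_cq <- apply(cqm, 1L, if (ref == "min") min else mean)
  q <- (1 + eff / 100) ^ (ref_cq - cqm)
  attr(q, "ref_cq") <- ref_cq
  q
}

extract_efficiencies <- function(efficiencies) {
  if (is.data.frame(efficiencies)) {
    stats::setNames(efficiencies$efficiency_pct, efficiencies$gene)
  } else if (is.list(efficiencies)) {
    vapply(efficiencies, `[[`, numeric(1), "efficiency_pct")
  } else if (is.numeric(efficiencies)) {
    if (is.null(names(efficiencies))) abort("efficiencies must be named by gene")
    efficiencies
  } else abort("unrecognized efficiencies argument")
}
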