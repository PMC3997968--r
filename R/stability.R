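#' Filter stably expressed miRNAs within a condition group
#'
#' A miRNA passes if (a) its expression variation stays at or below
#' `var_threshold_pct` in every designated pairwise comparison of the group,
#' and (b) its normalized linear reads reach `min_reads` in every sample of
#' the group (lowly expressed miRNAs are unreliable qPCR references).
#'
#' Variation is measured, per comparison, either from the slope-1 regression
#' residual on the log2 layer (`variation_metric = "residual"`, the default:
#' `(2^|r| - 1) * 100`, robust to residual library-size bias because the
#' intercept absorbs it) or as the naive percent difference of normalized
#' reads (`"direct"`: `|N_a - N_b| / N_b * 100`, with the second sample of
#' each pair as the denominator). A miRNA's variation is the maximum over the
#' group's comparisons.
#'
#' @param norm a `"mirna_norm"` object from [normalize_counts()].
#' @param comparisons a list of length-2 character vectors of sample ids,
#'   e.g. `list(c("uv", "ctrl"))`; for the `direct` metric the second element
#'   is the reference (denominator) sample.
#' @param var_threshold_pct maximum accepted percent variation. Default 7.
#' @param min_reads abundance floor on normalized linear reads, enforced in
#'   every sample of the group. Default 500.
#' @param variation_metric `"residual"` (default) or `"direct"`.
#' @param condition optional group label stored in the report.
#' @return Object of class `"stability_report"`: list with `condition`,
#'   `comparisons`, `variation_pct` (named, per miRNA, max over comparisons),
#'   `abundance_ok` (logical per miRNA), `passed` (character vector of stable
#'   miRNA ids), the thresholds and the metric used.
#' @export
filter_stable <- function(norm, comparisons,
                          var_threshold_pct = 7, min_reads = 500,
                          variation_metric = c("residual", "direct"),
                          condition = NULL) {
  if (!inherits(norm, "mirna_norm"))
    abort("norm must be a 'mirna_norm' object (see normalize_counts)")
  variation_metric <- match.arg(variation_metric)
  if (!is.list(comparisons) || length(comparisons) == 0L)
    abort("comparisons must be a nonempty list of sample pairs")
  samples <- unique(unlist(comparisons))
  unknown <- setdiff(samples, colnames(norm$linear))
  if (length(unknown))
    abort("unknown sample id(s) in comparisons: %s", paste(unknown, collapse = ", "))
  bad <- vapply(comparisons, function(p) length(p) != 2L, logical(1))
  if (any(bad)) abort("each comparison must name exactly two samples")

  mirnas <- rownames(norm$linear)
  var_by_cmp <- vapply(comparisons, function(p) {
    if (variation_metric == "residual") {
      fc <- fit_slope1(norm$log2[, p[2L]], norm$log2[, p[1L]],
                       sample_a = p[2L], sample_b = p[1L])
      percent_variation(fc)
    } else {
      a <- norm$linear[, p[1L]]
      b <- norm$linear[, p[2L]]
      abs(a - b) / b * 100
    }
  }, numeric(length(mirnas)))
  var_by_cmp <- matrix(var_by_cmp, nrow = length(mirnas),
                       dimnames = list(mirnas, NULL))
  variation_pct <- apply(var_by_cmp, 1L, max)

  abundance_ok <- apply(norm$linear[, samples, drop = FALSE] >= min_reads, 1L, all)
  passed <- mirnas[variation_pct <= var_threshold_pct & abundance_ok]

  structure(
    list(condition = condition %||% "group",
         comparisons = comparisons,
         samples = samples,
         variation_pct = variation_pct,
         abundance_ok = abundance_ok,
         passed = passed,
         var_threshold_pct = var_threshold_pct,
         min_reads = min_reads,
         variation_metric = variation_metric),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report '%s': %d/%d miRNAs stable\n",
              x$condition, length(x$passed), length(x$variation_pct)))
  cat(sprintf("  thresholds: variation <= %g%% (%s metric), >= %g normalized reads in all %d samples\n",
              x$var_threshold_pct, x$variation_metric, x$min_reads, length(x$samples)))
  if (length(x$passed))
    cat("  stable:", paste(utils::head(x$passed, 10), collapse = ", "),
        if (length(x$passed) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.stability_report <- function(x, ...) {
  data.frame(mirna = names(x$variation_pct),
             variation_pct = unname(x$variation_pct),
             abundance_ok = unname(x$abundance_ok),
             passed = names(x$variation_pct) %in% x$passed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect stable miRNA sets across conditions
#'
#' Computes the miRNAs stable in every condition and the full disjoint Venn
#' partition of the condition sets (the regions of a Venn diagram).
#'
#' @param reports a named list (>= 2 elements) of `"stability_report"`
#'   objects or character vectors of stable miRNA ids.
#' @return Object of class `"condition_intersection"`: list with
#'   `per_condition` (the input sets), `all_conditions` (their intersection)
#'   and `venn_partition` (named list; names like `"uv&heat"` give the
#'   conditions whose exclusive overlap the region is; regions are disjoint
#'   and union to the union of all sets).
#' @export
intersect_conditions <- function(reports) {
  if (!is.list(reports) || length(reports) < 2L)
    abort("need at least 2 conditions to intersect")
  sets <- lapply(reports, function(r)
    if (inherits(r, "stability_report")) r$passed else as.character(r))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- sprintf("condition_%d", seq_along(sets))
  conds <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, conds))

  venn <- list()
  for (mask in seq_len(2 ^ length(conds) - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2 ^ (seq_along(conds) - 1L)))
    region <- universe[apply(membership, 1L, function(m) all(m == inset))]
    venn[[paste(conds[inset], collapse = "&")]] <- region
  }
  structure(
    list(per_condition = sets,
         all_conditions = Reduce(intersect, sets),
         venn_partition = venn),
    class = "condition_intersection")
}

#' @export
print.condition_intersection <- function(x, ...) {
  cat("Stable-set intersection across", length(x$per_condition), "conditions\n")
  for (nm in names(x$per_condition))
    cat(sprintf("  %s: %d stable\n", nm, length(x$per_condition[[nm]])))
  cat(sprintf("  stable in all: %d (%s)\n", length(x$all_conditions),
              paste(x$all_conditions, collapse = ", ")))
  invisible(x)
}

#' Assign candidate miRNAs to low/medium/high abundance tiers
#'
#' Reference candidates should span the dynamic range of the assay, so
#' candidates are tiered by their mean normalized reads across samples.
#' A value exactly on a boundary goes to the higher tier.
#'
#' @param norm a `"mirna_norm"` object.
#' @param candidates character vector of miRNA ids present in `norm`.
#' @param boundaries two strictly increasing numbers: the low/medium and
#'   medium/high cut points on mean normalized reads.
#' @param samples sample ids over which to average; default all samples.
#' @return list with elements `low`, `medium`, `high` (character vectors
#'   partitioning `candidates`) and `mean_reads` (named numeric).
#' @export
tier_by_abundance <- function(norm, candidates, boundaries = c(2000, 1e5),
                              samples = NULL) {
  if (!inherits(norm, "mirna_norm")) abort("norm must be a 'mirna_norm' object")
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    abort("boundaries must be two strictly increasing numbers")
  missing <- setdiff(candidates, rownames(norm$linear))
  if (length(missing))
    abort("candidate(s) absent from matrix: %s", paste(missing, collapse = ", "))
  samples <- samples %||% colnames(norm$linear)
  m <- rowMeans(norm$linear[candidates, samples, drop = FALSE])
  tier <- ifelse(m >= boundaries[2L], "high",
                 ifelse(m >= boundaries[1L], "medium", "low"))
  list(low = candidates[tier == "low"],
       medium = candidates[tier == "medium"],
       high = candidates[tier == "high"],
       mean_reads = m)
}
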