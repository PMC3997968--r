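# End-to-end orchestration of the two arms:
#   discovery: counts -> normalize -> slope-1 fold changes -> stability
#              filter per condition -> cross-condition intersection -> tiers
#   validation: Cq panel + dilution series -> replicate collapse ->
#               efficiency fits -> relative quantities -> geNorm report

#' Default pipeline configuration
#'
#' @param pseudocount pseudocount for the log2 layer. Default 10.
#' @param var_threshold_pct stability variation threshold (%). Default 7.
#' @param min_reads abundance floor on normalized reads. Default 500.
#' @param variation_metric `"residual"` or `"direct"`.
#' @param comparisons named list: condition -> list of sample-id pairs.
#' @param tier_boundaries low/medium and medium/high abundance cut points.
#' @param m_cutoff,v_cutoff geNorm decision thresholds.
#' @param ref_cq `"min"` or `"mean"` reference Cq.
#' @param decimal_comma passed to [read_count_table()].
#' @return a named list of configuration values.
#' @export
pipeline_config <- function(pseudocount = 10, var_threshold_pct = 7,
                            min_reads = 500,
                            variation_metric = "residual",
                            comparisons = NULL,
                            tier_boundaries = c(2000, 1e5),
                            m_cutoff = 0.5, v_cutoff = 0.15,
                            ref_cq = "min", decimal_comma = "auto") {
  list(pseudocount = pseudocount, var_threshold_pct = var_threshold_pct,
       min_reads = min_reads, variation_metric = variation_metric,
       comparisons = comparisons, tier_boundaries = tier_boundaries,
       m_cutoff = m_cutoff, v_cutoff = v_cutoff, ref_cq = ref_cq,
       decimal_comma = decimal_comma)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort("[stage %s] %s", stage, conditionMessage(e)))
}

#' Run the discovery arm: counts to stable candidate sets
#'
#' @param counts path to a count table (see [read_count_table()]) or a
#'   numeric count matrix.
#' @param config list from [pipeline_config()]; `config$comparisons` must
#'   name, per condition, the sample pairs to compare. If omitted and the
#'   matrix has `<x>_ctrl`/`<x>_stress` column pairs, those are used.
#' @param out optional output directory; when given, per-condition
#'   stability TSVs, an intersection JSON, tier JSON and a run manifest are
#'   written there.
#' @return list with `norm`, `reports` (per condition), `intersection`
#'   (`NULL` with a single condition), `tiers` (per condition, stable
#'   candidates tiered by abundance) and `manifest`.
#' @export
run_discovery <- function(counts, config = pipeline_config(), out = NULL) {
  input_path <- if (is.character(counts)) counts else NA_character_
  mat <- with_stage("read_counts",
    if (is.character(counts))
      read_count_table(counts, decimal_comma = config$decimal_comma)
    else as_count_matrix(counts))
  norm <- with_stage("normalize", normalize_counts(mat, config$pseudocount))

  comparisons <- config$comparisons %||% infer_comparisons(colnames(mat))
  if (is.null(comparisons))
    abort("[stage filter] config$comparisons is required (no <x>_ctrl/<x>_stress column pairs found)")

  reports <- lapply(names(comparisons), function(cond)
    with_stage(paste0("filter:", cond),
      filter_stable(norm, comparisons[[cond]],
                    var_threshold_pct = config$var_threshold_pct,
                    min_reads = config$min_reads,
                    variation_metric = config$variation_metric,
                    condition = cond)))
  names(reports) <- names(comparisons)

  intersection <- if (length(reports) >= 2L)
    with_stage("intersect", intersect_conditions(reports)) else NULL

  tiers <- lapply(reports, function(r)
    if (length(r$passed))
      with_stage("tier", tier_by_abundance(norm, r$passed,
                                           boundaries = config$tier_boundaries,
                                           samples = r$samples))
    else NULL)

  result <- list(norm = norm, reports = reports, intersection = intersection,
                 tiers = tiers)
  result$manifest <- if (!is.null(out))
    write_discovery_outputs(result, config, input_path, out) else NULL
  result
}

infer_comparisons <- function(samples) {
  stress <- grep("_stress$", samples, value = TRUE)
  conds <- sub("_stress$", "", stress)
  conds <- conds[paste0(conds, "_ctrl") %in% samples]
  if (!length(conds)) return(NULL)
  stats::setNames(lapply(conds, function(cond)
    list(c(paste0(cond, "_stress"), paste0(cond, "_ctrl")))), conds)
}

#' Run the validation arm: Cq + dilution data to a geNorm report
#'
#' @param cq path to (or data.frame of) a long-format Cq panel.
#' @param dilutions path to (or data.frame of) a dilution-series table.
#' @param config list from [pipeline_config()].
#' @param out optional output directory for the efficiency table,
#'   relative-quantity matrix, geNorm JSON and manifest.
#' @return list with `efficiency` (table), `mean_cq`, `rq` (relative
#'   quantities), `genorm` (the fitted `"genorm"` object) and `manifest`.
#' @export
run_validation <- function(cq, dilutions, config = pipeline_config(),
                           out = NULL) {
  panel <- with_stage("read_cq", read_cq_panel(cq))
  dil <- with_stage("read_dilutions", read_dilution_series(dilutions))
  cq_genes <- unique(panel$gene)
  dil_genes <- unique(dil$gene)
  if (!setequal(cq_genes, dil_genes))
    abort("[stage gene_coverage] Cq panel and dilution series cover different genes; only in panel: {%s}; only in dilutions: {%s}",
          paste(setdiff(cq_genes, dil_genes), collapse = ", "),
          paste(setdiff(dil_genes, cq_genes), collapse = ", "))

  mean_cq <- with_stage("collapse", collapse_replicates(panel))
  eff <- with_stage("fit_efficiency", efficiency_table(dil))
  rq <- with_stage("relative_quantities",
                   relative_quantities(mean_cq, eff, ref = config$ref_cq))
  gn <- with_stage("genorm",
                   genorm(rq, m_cutoff = config$m_cutoff,
                          v_cutoff = config$v_cutoff))
  result <- list(efficiency = eff, mean_cq = mean_cq, rq = rq, genorm = gn)
  result$manifest <- if (!is.null(out))
    write_validation_outputs(result, config, out) else NULL
  result
}

write_discovery_outputs <- function(result, config, input_path, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cond in names(result$reports)) {
    f <- file.path(out, sprintf("stability_%s.tsv", cond))
    write_stability_tsv(result$reports[[cond]], f)
    files <- c(files, f)
  }
  if (!is.null(result$intersection)) {
    f <- file.path(out, "intersection.json")
    write_stability_json(result$intersection, f)
    files <- c(files, f)
  }
  f <- file.path(out, "tiers.json")
  jsonlite::write_json(lapply(result$tiers, function(t)
    if (is.null(t)) list() else t[c("low", "medium", "high")]),
    f, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  write_manifest(out, "discovery", config, input_path, files)
}

write_validation_outputs <- function(result, config, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  f_eff <- file.path(out, "efficiency.csv")
  utils::write.csv(result$efficiency, f_eff, row.names = FALSE, quote = FALSE)
  f_rq <- file.path(out, "relative_quantities.tsv")
  utils::write.table(data.frame(gene = rownames(result$rq), result$rq,
                                check.names = FALSE),
                     f_rq, sep = "\t", quote = FALSE, row.names = FALSE)
  f_gn <- file.path(out, "genorm.json")
  gn <- result$genorm
  jsonlite::write_json(
    list(m_values = as.list(gn$m),
         m_pass = as.list(gn$m_pass),
         m_cutoff = gn$m_cutoff,
         ranking = gn$ranking$ranking,
         exclusion_order = gn$ranking$exclusion_order,
         stage_m = lapply(gn$ranking$stages, function(s) as.list(s$m)),
         v = if (is.null(gn$v)) NULL else as.list(gn$v$v),
         v_cutoff = gn$v_cutoff,
         recommended_n = gn$recommended_n,
         cv = as.list(gn$cv)),
    f_gn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out, "validation", config, NA_character_,
                 c(f_eff, f_rq, f_gn))
}

# Manifest: config snapshot + md5 of every output, enough to reproduce the
# run. Deliberately contains no timestamps so repeated runs are
# byte-identical.
write_manifest <- function(out, arm, config, input_path, files) {
  manifest <- list(
    arm = arm,
    input = if (is.na(input_path)) NULL else input_path,
    config = config[!vapply(config, is.null, logical(1))],
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
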