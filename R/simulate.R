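# Seeded simulators with known ground truth, so every pipeline stage can be
# tested without external data. Randomness uses R's default Mersenne-Twister
# generator; a fixed seed gives identical output on every platform.

#' Simulation configuration
#'
#' Bundles the generator parameters with defaults emulating the study
#' design this package targets: single-replicate small RNA-seq libraries
#' per stress/control pair across several stress conditions, read counts
#' spanning roughly 500 to 375,000, overdispersed counts with ~2% technical
#' CV, unstable genes with log-normal condition effects, and qPCR panels
#' with 3 biological x 3 technical replicates and primer efficiencies
#' between 89 and 120%.
#'
#' @param n_mirnas number of miRNAs.
#' @param conditions character vector of condition (stress) names; each gets
#'   a matched control and a stress library.
#' @param stable_fraction fraction of miRNAs with zero condition effect.
#' @param mean_expression_range base mean read counts, drawn log-uniformly.
#' @param dispersion squared coefficient of variation of the multiplicative
#'   count noise (gamma with mean 1, variance `dispersion`); 0 turns noise
#'   off so counts are the rounded expected means. Default 4e-4 (2% CV).
#' @param library_size_range per-sample library-size factors, drawn
#'   log-uniformly.
#' @param unstable_lfc_sd SD (log2 units) of the condition effect planted in
#'   unstable miRNAs. Default 0.5.
#' @param cq_intercept_range range of per-gene Cq intercepts (Cq at
#'   quantity 1).
#' @param technical_sd SD of Gaussian technical noise on Cq, in cycles.
#'   Default `log2(1.02)` (~0.0286), i.e. a 2% CV on quantities at 100%
#'   efficiency.
#' @param efficiency_range range (%) of true primer efficiencies.
#' @param n_biological,n_technical qPCR replicate structure. Defaults 3 x 3.
#' @return a list of class `"sim_config"`.
#' @export
simulation_config <- function(n_mirnas = 200,
                              conditions = c("UV", "heat", "hypoxia", "hypoxia_hif1"),
                              stable_fraction = 0.3,
                              mean_expression_range = c(500, 375000),
                              dispersion = 4e-4,
                              library_size_range = c(0.5, 2),
                              unstable_lfc_sd = 0.5,
                              cq_intercept_range = c(15, 30),
                              technical_sd = log2(1.02),
                              efficiency_range = c(89, 120),
                              n_biological = 3,
                              n_technical = 3) {
  cfg <- list(n_mirnas = n_mirnas, conditions = conditions,
              stable_fraction = stable_fraction,
              mean_expression_range = mean_expression_range,
              dispersion = dispersion,
              library_size_range = library_size_range,
              unstable_lfc_sd = unstable_lfc_sd,
              cq_intercept_range = cq_intercept_range,
              technical_sd = technical_sd,
              efficiency_range = efficiency_range,
              n_biological = n_biological, n_technical = n_technical)
  if (cfg$n_mirnas < 1 || length(cfg$conditions) < 1)
    abort("degenerate configuration: need >= 1 miRNA and >= 1 condition")
  if (cfg$stable_fraction < 0 || cfg$stable_fraction > 1)
    abort("stable_fraction must be in [0, 1]")
  if (cfg$dispersion < 0 || cfg$technical_sd < 0)
    abort("dispersion and technical_sd must be nonnegative")
  if (any(cfg$mean_expression_range <= 0) || any(cfg$library_size_range <= 0))
    abort("expression and library-size ranges must be positive")
  structure(cfg, class = "sim_config")
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1L]), log(range[2L])))
}

# mean-1 multiplicative gamma noise with variance = dispersion
gamma_noise <- function(n, dispersion) {
  if (dispersion == 0) rep(1, n)
  else stats::rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
}

#' Simulate a raw miRNA count matrix with planted truth
#'
#' Expected counts are `base mean x condition effect x library factor`;
#' planted stable miRNAs carry zero condition effect in every condition,
#' unstable ones a per-condition log2 effect drawn from
#' `N(0, unstable_lfc_sd)` and centered to mean zero across miRNAs within
#' each condition (under per-library normalization a global mean log2 shift
#' is indistinguishable from a library-size factor, so only centered effects
#' are identifiable as fold changes). Observed counts are the expected means times
#' mean-1 gamma noise (variance = `dispersion`), rounded; with
#' `dispersion = 0` the counts equal the rounded expected means.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return list with `counts` (matrix, samples `<condition>_ctrl` /
#'   `<condition>_stress`), `truth` (list: `stable_set`, `lfc` gene x
#'   condition matrix, `base_means`, `library_factors`) and `comparisons`
#'   (per-condition stress-vs-control sample pairs, ready for
#'   [filter_stable()]).
#' @export
simulate_counts <- function(cfg = simulation_config(), seed = 1) {
  set.seed(seed)
  genes <- sprintf("mir-sim-%03d", seq_len(cfg$n_mirnas))
  samples <- as.vector(rbind(paste0(cfg$conditions, "_ctrl"),
                             paste0(cfg$conditions, "_stress")))
  base <- runif_log(cfg$n_mirnas, cfg$mean_expression_range)
  n_stable <- round(cfg$stable_fraction * cfg$n_mirnas)
  stable <- sort(sample(genes, n_stable))
  lfc <- matrix(0, cfg$n_mirnas, length(cfg$conditions),
                dimnames = list(genes, cfg$conditions))
  unstable <- setdiff(genes, stable)
  if (length(unstable)) {
    draws <- matrix(stats::rnorm(length(unstable) * length(cfg$conditions),
                                 sd = cfg$unstable_lfc_sd),
                    length(unstable))
    # center planted effects per condition: under per-library normalization a
    # global mean log2 shift is indistinguishable from a library-size factor
    # (parameterized separately), so only centered effects are identifiable
    if (length(unstable) > 1L)
      draws <- sweep(draws, 2L, colMeans(draws), "-")
    lfc[unstable, ] <- draws
  }
  libfac <- stats::setNames(runif_log(length(samples), cfg$library_size_range),
                            samples)
  mu <- matrix(0, cfg$n_mirnas, length(samples),
               dimnames = list(genes, samples))
  for (i in seq_along(cfg$conditions)) {
    ctrl <- paste0(cfg$conditions[i], "_ctrl")
    stress <- paste0(cfg$conditions[i], "_stress")
    mu[, ctrl] <- base * libfac[ctrl]
    mu[, stress] <- base * 2 ^ lfc[, i] * libfac[stress]
  }
  counts <- round(mu * gamma_noise(length(mu), cfg$dispersion))
  comparisons <- lapply(cfg$conditions, function(cond)
    list(c(paste0(cond, "_stress"), paste0(cond, "_ctrl"))))
  names(comparisons) <- cfg$conditions
  list(counts = counts,
       truth = list(stable_set = stable, lfc = lfc,
                    base_means = base, library_factors = libfac),
       comparisons = comparisons)
}

#' Simulate a Cq panel from true relative quantities
#'
#' The measurement model is `Cq = intercept - log_(1+E/100)(quantity)` plus
#' Gaussian technical noise per replicate: at 100% efficiency, halving a
#' quantity raises Cq by exactly one cycle.
#'
#' @param quantities gene x sample matrix of positive true quantities (the
#'   samples are the biological samples).
#' @param efficiencies percent efficiencies, recycled or named per gene.
#' @param cq_intercept Cq at quantity 1, recycled or named per gene.
#' @param technical_sd SD of the technical noise in cycles; 0 for a
#'   noiseless panel.
#' @param n_technical technical replicates per (gene, sample). Default 3.
#' @param seed integer seed.
#' @return long-format data.frame (gene, sample, replicate, cq) as read by
#'   [collapse_replicates()].
#' @export
simulate_cq_panel <- function(quantities, efficiencies = 100,
                              cq_intercept = 30, technical_sd = 0,
                              n_technical = 3, seed = 1) {
  if (!is.matrix(quantities) || any(quantities <= 0))
    abort("quantities must be a positive gene x sample matrix")
  set.seed(seed)
  genes <- rownames(quantities) %||% sprintf("gene_%d", seq_len(nrow(quantities)))
  samples <- colnames(quantities) %||% sprintf("sample_%d", seq_len(ncol(quantities)))
  eff <- recycle_by_gene(efficiencies, genes, "efficiencies")
  icpt <- recycle_by_gene(cq_intercept, genes, "cq_intercept")
  if (any(eff <= -100)) abort("efficiencies must exceed -100%%")
  base_cq <- icpt - log2(quantities) / log2(1 + eff / 100)
  out <- expand.grid(replicate = seq_len(n_technical), sample = samples,
                     gene = genes, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)[, c("gene", "sample", "replicate")]
  cq <- base_cq[cbind(match(out$gene, genes), match(out$sample, samples))]
  out$cq <- cq + stats::rnorm(nrow(out), sd = technical_sd)
  out
}

recycle_by_gene <- function(x, genes, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(genes, names(x))
    if (length(missing)) abort("%s missing for gene(s): %s", what,
                               paste(missing, collapse = ", "))
    return(x[genes])
  }
  stats::setNames(rep_len(x, length(genes)), genes)
}

#' Simulate a dilution series with known amplification efficiency
#'
#' Cq values follow `Cq = cq0 + log10(dilution) / log10(1 + E/100)` plus
#' optional Gaussian noise, so that [fit_efficiency()] at zero noise
#' recovers the true efficiency exactly.
#'
#' @param efficiency_pct true percent efficiency (> -100).
#' @param n_dilutions number of dilution points (>= 3).
#' @param step fold-dilution between consecutive points. Default 10.
#' @param sigma SD of Gaussian Cq noise per point. Default 0.
#' @param n_replicates replicate measurements per dilution. Default 1.
#' @param cq0 Cq of the undiluted sample. Default 18.
#' @param gene gene label.
#' @param seed integer seed.
#' @return data.frame (gene, dilution_factor, cq) as read by
#'   [fit_efficiency()].
#' @export
simulate_dilution_series <- function(efficiency_pct, n_dilutions = 5,
                                     step = 10, sigma = 0, n_replicates = 1,
                                     cq0 = 18, gene = "gene", seed = 1) {
  if (efficiency_pct <= -100) abort("efficiency_pct must exceed -100")
  if (n_dilutions < 3) abort("need at least 3 dilutions")
  if (step <= 1) abort("dilution step must exceed 1")
  set.seed(seed)
  d <- rep(step ^ (seq_len(n_dilutions) - 1L), each = n_replicates)
  cq <- cq0 + log10(d) / log10(1 + efficiency_pct / 100) +
    stats::rnorm(length(d), sd = sigma)
  data.frame(gene = gene, dilution_factor = d, cq = cq,
             stringsAsFactors = FALSE)
}
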