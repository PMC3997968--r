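# geNorm reference-gene stability analysis, implemented from first
# principles on a genes x samples matrix of positive relative quantities.
# All statistics are built from log2 ratios, so they are invariant to
# per-gene and per-sample positive rescaling.

validate_rq <- function(rq, min_genes = 2L) {
  if (!is.matrix(rq) || !is.numeric(rq))
    abort("relative quantities must be a numeric matrix (genes x samples)")
  if (any(!is.finite(rq)) || any(rq <= 0))
    abort("relative quantities must be finite and strictly positive")
  if (nrow(rq) < min_genes)
    abort("need at least %d genes (got %d)", min_genes, nrow(rq))
  if (ncol(rq) < 2L) abort("need at least 2 samples (got %d)", ncol(rq))
  if (is.null(rownames(rq))) rownames(rq) <- sprintf("gene_%d", seq_len(nrow(rq)))
  rq
}

#' geNorm M values
#'
#' For each candidate gene j, M_j is the mean over all other candidates k of
#' the standard deviation (n-1 denominator) across samples of
#' `log2(q_j / q_k)`. Lower M means more stable expression relative to the
#' rest of the panel.
#'
#' @param rq genes x samples matrix of positive relative quantities.
#' @return named numeric vector of M values.
#' @export
genorm_m <- function(rq) {
  rq <- validate_rq(rq, min_genes = 2L)
  l <- log2(rq)
  g <- nrow(l)
  v <- matrix(0, g, g)
  for (j in seq_len(g - 1L)) {
    for (k in (j + 1L):g) {
      v[j, k] <- v[k, j] <- stats::sd(l[j, ] - l[k, ])
    }
  }
  stats::setNames(rowSums(v) / (g - 1L), rownames(rq))
}

#' Stepwise geNorm stability ranking
#'
#' Repeatedly computes M values and removes the gene with the highest M
#' (least stable) until two genes remain; those two cannot be distinguished
#' by M and share the top rank. Ties on M are broken deterministically: the
#' alphabetically later gene identifier is excluded first.
#'
#' @param rq genes x samples matrix of positive relative quantities.
#' @return Object of class `"genorm_ranking"`: list with
#'   \describe{
#'     \item{stages}{list, one element per exclusion stage, each holding the
#'       gene set and its M values at that stage.}
#'     \item{exclusion_order}{genes in the order removed (least stable
#'       first).}
#'     \item{ranking}{genes from most to least stable: the final pair
#'       (alphabetical) followed by the exclusions in reverse order.}
#'     \item{final_pair}{the two genes never excluded.}
#'     \item{m_full}{M values of the complete panel (stage 1).}
#'   }
#' @export
stepwise_rank <- function(rq) {
  rq <- validate_rq(rq, min_genes = 2L)
  stages <- list()
  excluded <- character(0)
  current <- rq
  repeat {
    m <- genorm_m(current)
    stages[[length(stages) + 1L]] <- list(genes = rownames(current), m = m)
    if (nrow(current) <= 2L) break
    worst <- max(m)
    # alphabetically last among ties leaves first
    drop_gene <- max(names(m)[m == worst])
    excluded <- c(excluded, drop_gene)
    current <- current[setdiff(rownames(current), drop_gene), , drop = FALSE]
  }
  final_pair <- sort(rownames(current))
  structure(
    list(stages = stages,
         exclusion_order = excluded,
         ranking = c(final_pair, rev(excluded)),
         final_pair = final_pair,
         m_full = stages[[1L]]$m),
    class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm stepwise ranking (most to least stable):\n  ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Per-sample normalization factors
#'
#' The normalization factor of a sample is the geometric mean of the
#' relative quantities of the chosen reference genes in that sample.
#'
#' @param rq genes x samples matrix of positive relative quantities.
#' @param genes nonempty subset of rownames(rq).
#' @return named numeric vector, one positive factor per sample.
#' @export
normalization_factor <- function(rq, genes) {
  rq <- validate_rq(rq, min_genes = 1L)
  if (length(genes) == 0L) abort("gene subset must be nonempty")
  missing <- setdiff(genes, rownames(rq))
  if (length(missing)) abort("gene(s) not in matrix: %s", paste(missing, collapse = ", "))
  exp(colMeans(log(rq[genes, , drop = FALSE])))
}

#' Pairwise variation V(n/n+1) and recommended reference-gene count
#'
#' For each n from 2 to G-1, V(n/n+1) is the standard deviation across
#' samples of `log2(NF_n / NF_{n+1})`, where NF_n is the normalization
#' factor built from the n best-ranked genes. The recommended number of
#' reference genes is the smallest n with V(n/n+1) below the cutoff
#' (conventionally 0.15); if no V clears the cutoff, all G genes are
#' recommended, with a warning.
#'
#' @param rq genes x samples matrix of positive relative quantities.
#' @param ranking a `"genorm_ranking"` from [stepwise_rank()], or a character
#'   vector of genes from most to least stable. Computed if omitted.
#' @param cutoff decision threshold on V. Default 0.15.
#' @return Object of class `"pairwise_variation"`: list with `v` (named
#'   numeric, names `"2/3"`, `"3/4"`, ...), `cutoff` and `recommended_n`.
#' @export
pairwise_variation <- function(rq, ranking = NULL, cutoff = 0.15) {
  rq <- validate_rq(rq, min_genes = 3L)
  if (is.null(ranking)) ranking <- stepwise_rank(rq)
  order <- if (inherits(ranking, "genorm_ranking")) ranking$ranking else as.character(ranking)
  if (!setequal(order, rownames(rq)))
    abort("ranking must contain exactly the genes of the matrix")
  g <- nrow(rq)
  nf <- lapply(2:g, function(n) normalization_factor(rq, order[seq_len(n)]))
  names(nf) <- 2:g
  v <- vapply(2:(g - 1L), function(n) {
    stats::sd(log2(nf[[as.character(n)]] / nf[[as.character(n + 1L)]]))
  }, numeric(1))
  names(v) <- sprintf("%d/%d", 2:(g - 1L), 3:g)
  below <- which(v < cutoff)
  if (length(below)) {
    recommended_n <- (2:(g - 1L))[below[1L]]
  } else {
    recommended_n <- g
    warn("no pairwise variation below the %g cutoff; recommending all %d genes",
         cutoff, g)
  }
  structure(list(v = v, cutoff = cutoff, recommended_n = recommended_n),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("Pairwise variation V(n/n+1):\n")
  print(round(x$v, 4))
  cat(sprintf("Recommended number of reference genes (cutoff %g): %d\n",
              x$cutoff, x$recommended_n))
  invisible(x)
}

#' Coefficient of variation of normalized relative quantities
#'
#' Each gene's quantities are divided by the per-sample normalization factor
#' and the CV (sd/mean, linear scale, n-1 sd) of the normalized series is
#' reported. Stable reference genes typically show CV below 0.2 in
#' homogeneous sample panels.
#'
#' @param rq genes x samples matrix of positive relative quantities.
#' @param nf per-sample normalization factors (from
#'   [normalization_factor()] on the recommended gene subset).
#' @return named numeric vector of CVs.
#' @export
gene_cv <- function(rq, nf) {
  rq <- validate_rq(rq, min_genes = 1L)
  if (length(nf) != ncol(rq)) abort("need one normalization factor per sample")
  if (any(nf <= 0)) abort("normalization factors must be positive")
  normalized <- sweep(rq, 2L, nf, "/")
  apply(normalized, 1L, function(x) stats::sd(x) / mean(x))
}

#' Classify genes by the geNorm M cutoff
#'
#' A gene passes if its M value is strictly below the cutoff (conventionally
#' 0.5 for homogeneous panels); M equal to the cutoff fails.
#'
#' @param m named numeric vector of M values.
#' @param cutoff stability threshold. Default 0.5.
#' @return named logical vector.
#' @export
classify_m <- function(m, cutoff = 0.5) {
  if (any(m < 0)) abort("M values cannot be negative")
  m < cutoff
}

#' geNorm stability analysis of a relative-quantity panel
#'
#' The one-stop fitting function: computes full-panel M values, the stepwise
#' exclusion ranking, the pairwise-variation series with its reference-count
#' recommendation, and per-gene CVs normalized by the recommended reference
#' set.
#'
#' @param rq genes x samples matrix of positive relative quantities, e.g.
#'   from [relative_quantities()].
#' @param m_cutoff stability classification threshold on M. Default 0.5.
#' @param v_cutoff pairwise-variation cutoff. Default 0.15.
#' @return Object of class `"genorm"`: list with `rq`, `m` (full-panel M),
#'   `m_pass` (M < m_cutoff), `ranking` (`"genorm_ranking"`), `v`
#'   (`"pairwise_variation"`, `NULL` for 2-gene panels), `recommended_n`,
#'   `nf` (normalization factors of the recommended set), `cv`, and the
#'   cutoffs.
#' @examples
#' set.seed(1)
#' rq <- matrix(2 ^ rnorm(24, sd = 0.1), 4, 6,
#'              dimnames = list(paste0("mir-", 1:4), paste0("s", 1:6)))
#' fit <- genorm(rq)
#' fit
#' @export
genorm <- function(rq, m_cutoff = 0.5, v_cutoff = 0.15) {
  rq <- validate_rq(rq, min_genes = 2L)
  ranking <- stepwise_rank(rq)
  m <- ranking$m_full
  v <- if (nrow(rq) >= 3L) pairwise_variation(rq, ranking, cutoff = v_cutoff) else NULL
  recommended_n <- if (is.null(v)) nrow(rq) else v$recommended_n
  nf <- normalization_factor(rq, ranking$ranking[seq_len(recommended_n)])
  structure(
    list(rq = rq, m = m, m_pass = classify_m(m, m_cutoff),
         ranking = ranking, v = v, recommended_n = recommended_n,
         nf = nf, cv = gene_cv(rq, nf),
         m_cutoff = m_cutoff, v_cutoff = v_cutoff),
    class = "genorm")
}

#' @export
print.genorm <- function(x, ...) {
  cat(sprintf("geNorm analysis: %d genes x %d samples\n",
              nrow(x$rq), ncol(x$rq)))
  ord <- order(x$m)
  tab <- data.frame(M = round(x$m[ord], 4),
                    stable = ifelse(x$m_pass[ord], "yes", "no"),
                    CV = round(x$cv[names(x$m)[ord]], 4))
  print(tab)
  if (!is.null(x$v))
    cat(sprintf("V(2/3) = %.4f; recommended reference genes: %d (V cutoff %g)\n",
                x$v$v[1L], x$recommended_n, x$v_cutoff))
  invisible(x)
}

#' @export
summary.genorm <- function(object, ...) {
  cat("Stepwise exclusion (least stable removed first):\n")
  for (i in seq_along(object$ranking$stages)) {
    st <- object$ranking$stages[[i]]
    cat(sprintf("  stage %d (%d genes): %s\n", i, length(st$genes),
                paste(sprintf("%s M=%.3f", names(st$m), st$m), collapse = ", ")))
  }
  print(object)
  invisible(object)
}

#' Plot geNorm M values and pairwise variation
#'
#' Left panel: average M during stepwise exclusion (most stable genes on the
#' right). Right panel: V(n/n+1) bars with the decision cutoff.
#'
#' @param x a `"genorm"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.genorm <- function(x, ...) {
  old <- graphics::par(mfrow = if (is.null(x$v)) c(1, 1) else c(1, 2))
  on.exit(graphics::par(old))
  stages <- x$ranking$stages
  avg_m <- vapply(stages, function(s) mean(s$m), numeric(1))
  labels <- c(x$ranking$exclusion_order,
              paste(x$ranking$final_pair, collapse = " / "))
  graphics::plot(rev(avg_m), type = "b", xaxt = "n", xlab = "",
                 ylab = "Average expression stability M",
                 main = "Stepwise exclusion")
  graphics::axis(1, at = seq_along(avg_m), labels = rev(labels), las = 2,
                 cex.axis = 0.7)
  if (!is.null(x$v)) {
    graphics::barplot(x$v$v, ylab = "Pairwise variation V",
                      main = sprintf("Recommended n = %d", x$recommended_n), ...)
    graphics::abline(h = x$v$cutoff, lty = 2)
  }
  invisible(x)
}
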