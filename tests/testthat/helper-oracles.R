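# Independent brute-force oracles, written as naive re-derivations so they
# stay independent of the package's code paths.

# M value: average over all other genes of sd(log2 gene ratio) across samples
bf_m_values <- function(q) {
  g <- nrow(q)
  m <- numeric(g)
  for (j in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      ratios <- log2(q[j, ] / q[k, ])
      sds <- c(sds, sd(ratios))
    }
    m[j] <- mean(sds)
  }
  names(m) <- rownames(q)
  m
}

# stepwise exclusion, recomputing M from scratch at every stage;
# ties: alphabetically later gene leaves first
bf_stepwise <- function(q) {
  stages <- list()
  excluded <- character(0)
  while (TRUE) {
    m <- bf_m_values(q)
    stages[[length(stages) + 1L]] <- m
    if (nrow(q) <= 2L) break
    worst <- names(m)[m == max(m)]
    drop_gene <- sort(worst, decreasing = TRUE)[1L]
    excluded <- c(excluded, drop_gene)
    q <- q[rownames(q) != drop_gene, , drop = FALSE]
  }
  list(stages = stages, excluded = excluded,
       ranking = c(sort(rownames(q)), rev(excluded)))
}

# V(n/n+1) from explicit products (no shared code with the log-mean NF)
bf_v_series <- function(q, ranking) {
  g <- nrow(q)
  nf_of <- function(genes) {
    apply(q[genes, , drop = FALSE], 2, function(col) prod(col) ^ (1 / length(col)))
  }
  v <- numeric(0)
  for (n in 2:(g - 1L)) {
    a <- nf_of(ranking[1:n])
    b <- nf_of(ranking[1:(n + 1L)])
    v <- c(v, sd(log2(a / b)))
  }
  names(v) <- paste0(2:(g - 1L), "/", 3:g)
  v
}

# random positive relative-quantity matrix
random_rq <- function(g, s, sd = 0.4) {
  matrix(2 ^ rnorm(g * s, sd = sd), g, s,
         dimnames = list(sprintf("g%02d", seq_len(g)),
                         sprintf("s%02d", seq_len(s))))
}

# brute-force Venn region oracle: enumerate every membership signature
bf_venn <- function(sets) {
  universe <- unique(unlist(sets))
  regions <- list()
  for (id in universe) {
    sig <- paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
                 collapse = "&")
    regions[[sig]] <- c(regions[[sig]], id)
  }
  regions
}

# quantity panel with planted stable (2% technical CV) and unstable
# (log-normal condition effect, sd 0.5 log2 units) genes
planted_quantities <- function(n_stable = 4, n_unstable = 4, n_samples = 6,
                               stable_cv = 0.02, unstable_sd = 0.5) {
  genes <- c(sprintf("stab%02d", seq_len(n_stable)),
             sprintf("wob%02d", seq_len(n_unstable)))
  q <- matrix(1, length(genes), n_samples,
              dimnames = list(genes, sprintf("s%d", seq_len(n_samples))))
  noise_sd <- log2(1 + stable_cv)
  q <- q * 2 ^ matrix(rnorm(length(q), sd = noise_sd), nrow(q))
  idx <- seq_len(n_unstable) + n_stable
  q[idx, ] <- q[idx, ] * 2 ^ matrix(rnorm(n_unstable * n_samples, sd = unstable_sd),
                                    n_unstable)
  q
}

# three-gene panel engineered so V(2/3) is exactly `v`: two constant genes
# plus one whose log2 quantities have sample SD 3 * v
engineered_v23_panel <- function(v = 0.189, n_samples = 6) {
  d0 <- seq(-1, 1, length.out = n_samples)
  d <- d0 / sd(d0) * 3 * v
  rbind(ref_a = rep(1, n_samples),
        ref_b = rep(1, n_samples),
        wobbler = 2 ^ d)
}
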