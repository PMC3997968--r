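test_that("proportional genes have M = 0 and M is scale-invariant", {
  q <- rbind(a = c(1, 2, 4, 0.5), b = 3 * c(1, 2, 4, 0.5))
  expect_equal(unname(genorm_m(q)), c(0, 0))
  set.seed(51)
  q3 <- random_rq(5, 6)
  m1 <- genorm_m(q3)
  q3b <- q3
  q3b["g03", ] <- q3b["g03", ] * 10
  expect_equal(genorm_m(q3b), m1)
})

test_that("M values equal the brute-force double loop on random matrices", {
  set.seed(52)
  for (i in 1:20) {
    q <- random_rq(sample(2:7, 1), sample(3:10, 1))
    expect_equal(genorm_m(q), bf_m_values(q), tolerance = 1e-12)
  }
})

test_that("stepwise exclusion removes planted noise first", {
  set.seed(53)
  q <- random_rq(4, 8, sd = 0.02)
  q["g02", ] <- q["g02", ] * 2 ^ rnorm(8, sd = 1.5)  # one very noisy gene
  rk <- stepwise_rank(q)
  expect_equal(rk$exclusion_order[1], "g02")

  # two proportional genes + a noisy one: the pair wins with M = 0
  q3 <- rbind(p1 = c(1, 2, 3, 4), p2 = c(2, 4, 6, 8),
              noisy = c(1, 10, 0.2, 5))
  rk3 <- stepwise_rank(q3)
  expect_equal(rk3$final_pair, c("p1", "p2"))
  expect_equal(unname(rk3$stages[[2]]$m), c(0, 0))
})

test_that("stepwise ranking matches a brute-force re-computation at every stage", {
  set.seed(54)
  for (i in 1:10) {
    q <- random_rq(6, 8)
    rk <- stepwise_rank(q)
    bf <- bf_stepwise(q)
    expect_equal(rk$exclusion_order, bf$excluded)
    expect_equal(rk$ranking, bf$ranking)
    for (s in seq_along(bf$stages)) {
      nm <- sort(names(bf$stages[[s]]))
      expect_equal(rk$stages[[s]]$m[nm], bf$stages[[s]][nm], tolerance = 1e-12)
    }
  }
})

test_that("a two-gene panel degenerates to a joint final pair", {
  q <- random_rq(2, 5)
  rk <- stepwise_rank(q)
  expect_equal(rk$final_pair, c("g01", "g02"))
  expect_length(rk$exclusion_order, 0)
  expect_equal(rk$m_full[["g01"]], rk$m_full[["g02"]])
})

test_that("normalization factors are per-sample geometric means", {
  q <- rbind(a = c(1, 9), b = c(4, 1))
  colnames(q) <- c("s1", "s2")
  expect_equal(normalization_factor(q, "a"), c(s1 = 1, s2 = 9))
  expect_equal(normalization_factor(q, c("a", "b")), c(s1 = 2, s2 = 3))
  set.seed(55)
  qr <- random_rq(5, 7)
  expect_equal(normalization_factor(qr, rownames(qr)),
               exp(colMeans(log(qr))), tolerance = 1e-12)
  expect_error(normalization_factor(qr, character(0)), "nonempty")
})

test_that("pairwise variation is zero for proportional genes and matches brute force", {
  q <- rbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(0.5, 1, 2))
  pv <- pairwise_variation(q)
  expect_equal(unname(pv$v), 0)
  expect_equal(pv$recommended_n, 2)

  set.seed(56)
  for (i in 1:10) {
    qr <- random_rq(sample(4:7, 1), 8)
    rk <- stepwise_rank(qr)
    pv <- pairwise_variation(qr, rk, cutoff = 10)  # high cutoff: no warning path
    expect_equal(pv$v, bf_v_series(qr, rk$ranking), tolerance = 1e-12)
  }
})

test_that("recommended_n is monotone non-increasing in the cutoff", {
  set.seed(57)
  for (i in 1:10) {
    qr <- random_rq(6, 8)
    rec <- vapply(c(0.01, 0.05, 0.15, 0.3, 1), function(cut)
      suppressWarnings(pairwise_variation(qr, cutoff = cut)$recommended_n),
      numeric(1))
    expect_true(all(diff(rec) <= 0))
  }
})

test_that("when no V clears the cutoff, all genes are recommended with a warning", {
  set.seed(58)
  q <- random_rq(3, 6, sd = 1)  # noisy: V(2/3) far above 0.15
  expect_warning(pv <- pairwise_variation(q, cutoff = 1e-6), "all 3")
  expect_equal(pv$recommended_n, 3)
})

test_that("gene CV is sd/mean of the NF-normalized series", {
  q <- rbind(a = c(2, 2, 2, 6), b = c(1, 1, 1, 1))
  nf <- c(2, 2, 2, 2)
  cv <- gene_cv(q, nf)
  expect_equal(cv[["a"]], 1 / 1.5, tolerance = 1e-12)  # series (1,1,1,3)
  expect_equal(cv[["b"]], sd(c(0.5, 0.5, 0.5, 0.5)) / 0.5)
  # proportional to NF -> 0; invariant to per-gene rescaling
  expect_equal(gene_cv(rbind(x = 3 * nf), nf)[["x"]], 0)
  expect_equal(gene_cv(q * 5, nf), cv)
})

test_that("M classification is strict at the cutoff", {
  m <- c(good = 0, wobbly = 0.573, edge = 0.5)
  cls <- classify_m(m)
  expect_true(cls[["good"]])
  expect_false(cls[["wobbly"]])
  expect_false(cls[["edge"]])
  expect_error(classify_m(c(x = -0.1)), "negative")
})

test_that("geNorm statistics are invariant to gene and sample rescaling", {
  set.seed(59)
  for (i in 1:10) {
    q <- random_rq(5, 8)
    fit1 <- suppressWarnings(genorm(q))
    q2 <- q * matrix(runif(5, 0.1, 10), 5, 8)        # per-gene rescale
    q2 <- sweep(q2, 2, runif(8, 0.1, 10), "*")       # per-sample rescale
    fit2 <- suppressWarnings(genorm(q2))
    expect_equal(fit1$m, fit2$m, tolerance = 1e-10)
    expect_equal(fit1$ranking$ranking, fit2$ranking$ranking)
    expect_equal(fit1$v$v, fit2$v$v, tolerance = 1e-10)
    expect_equal(fit1$recommended_n, fit2$recommended_n)
  }
})

test_that("the genorm fit object prints, summarizes and plots", {
  set.seed(60)
  fit <- suppressWarnings(genorm(random_rq(4, 6, sd = 0.05)))
  expect_s3_class(fit, "genorm")
  expect_output(print(fit), "geNorm analysis")
  expect_output(summary(fit), "Stepwise exclusion")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
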