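make_panel <- function(cq_by_gene_sample, n_rep = 3, jitter = 0) {
  # cq_by_gene_sample: gene x sample matrix of replicate-mean targets
  do.call(rbind, lapply(rownames(cq_by_gene_sample), function(g)
    do.call(rbind, lapply(colnames(cq_by_gene_sample), function(s)
      data.frame(gene = g, sample = s, replicate = seq_len(n_rep),
                 cq = cq_by_gene_sample[g, s] + jitter * (seq_len(n_rep) - 2),
                 stringsAsFactors = FALSE)))))
}

test_that("technical replicates collapse to their Cq mean with QC spread", {
  panel <- data.frame(gene = "g1", sample = "s1", replicate = 1:3,
                      cq = c(20, 20, 20))
  out <- collapse_replicates(panel)
  expect_equal(out$cq, 20)
  expect_equal(out$cq_sd, 0)
  two <- collapse_replicates(data.frame(gene = "g", sample = "s",
                                        replicate = 1:2, cq = c(20, 21)))
  expect_equal(two$cq, 20.5)
  expect_equal(two$n_reps, 2L)
})

test_that("missing (gene, sample) combinations are reported, not dropped", {
  panel <- data.frame(gene = c("g1", "g1", "g2"),
                      sample = c("s1", "s2", "s1"),
                      replicate = 1, cq = c(20, 21, 22))
  expect_error(collapse_replicates(panel), "(g2, s2)", fixed = TRUE)
})

test_that("efficiency follows E% = (10^(1/slope) - 1) * 100", {
  perfect <- data.frame(dilution_factor = 10 ^ (0:4),
                        cq = 20 + (0:4) / log10(2))  # slope 1/log10(2)
  fit <- fit_efficiency(perfect)
  expect_equal(fit$efficiency_pct, 100)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1 / log10(2))

  steep <- data.frame(dilution_factor = 10 ^ (0:3), cq = 20 + (0:3))
  expect_equal(fit_efficiency(steep)$efficiency_pct, 900)

  expect_error(fit_efficiency(data.frame(dilution_factor = c(1, 10, 10),
                                         cq = c(1, 2, 2))), "3 distinct")
  expect_warning(fit_efficiency(data.frame(dilution_factor = 10 ^ (0:3),
                                           cq = 20 - (0:3) * 3.3)),
                 "negative slope")
})

test_that("noiseless fits are exact for any dilution spacing", {
  set.seed(41)
  for (i in 1:10) {
    e_true <- runif(1, 80, 125)
    steps <- sort(runif(5, 0, 5))
    series <- data.frame(dilution_factor = 10 ^ steps,
                         cq = 15 + steps / log10(1 + e_true / 100))
    fit <- fit_efficiency(series)
    expect_equal(fit$efficiency_pct, e_true, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("noisy dilution series recover efficiency within a few points", {
  errs <- vapply(1:100, function(seed) {
    s <- simulate_dilution_series(95, n_dilutions = 5, step = 10,
                                  sigma = 0.1, n_replicates = 3, seed = seed)
    fit_efficiency(s)$efficiency_pct - 95
  }, numeric(1))
  expect_true(all(abs(errs) < 5))
})

test_that("recovered efficiencies stay inside the realistic qPCR envelope", {
  # true efficiencies drawn well inside 89-119.6%; modest Cq noise
  effs <- vapply(1:50, function(seed) {
    set.seed(seed)
    e_true <- runif(1, 95, 115)
    s <- simulate_dilution_series(e_true, n_dilutions = 5, step = 10,
                                  sigma = 0.15, n_replicates = 3, seed = seed)
    fit_efficiency(s)$efficiency_pct
  }, numeric(1))
  expect_true(all(effs > 89 & effs < 119.6))
})

test_that("relative quantities halve per cycle at 100% efficiency", {
  cqm <- matrix(c(20, 21), 1, 2, dimnames = list("g", c("s1", "s2")))
  q <- relative_quantities(cqm, c(g = 100))
  expect_equal(unname(q["g", ]), c(1, 0.5))
  flat <- relative_quantities(matrix(25, 1, 3, dimnames = list("g", 1:3)),
                              c(g = 100))
  expect_true(all(flat == 1))
})

test_that("efficiency correction uses (1+E/100) as the base", {
  cqm <- matrix(c(20, 22), 1, 2, dimnames = list("g", c("ref", "late")))
  q <- relative_quantities(cqm, c(g = 90))
  expect_equal(unname(q["g", "late"]), 1 / 1.9 ^ 2, tolerance = 1e-12)
  expect_equal(unname(q["g", "late"]), 0.2770, tolerance = 1e-4)
  # cross-check in log space
  expect_equal(log(unname(q["g", "late"])), -2 * log(1.9))
})

test_that("relative quantities are invariant to per-gene Cq shifts", {
  set.seed(43)
  cqm <- matrix(runif(12, 18, 28), 3, 4,
                dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  eff <- c(a = 100, b = 92.8, c = 119.6)
  q1 <- relative_quantities(cqm, eff)
  shifted <- cqm
  shifted["b", ] <- shifted["b", ] + 3.7
  q2 <- relative_quantities(shifted, eff)
  expect_equal(q1, q2, ignore_attr = TRUE)
  # reference sample has quantity exactly 1, everything else below
  expect_equal(unname(apply(q1, 1, max)), c(1, 1, 1))
  # at 100% efficiency this is the classic 2^(-deltaCq)
  dcq <- cqm["a", ] - min(cqm["a", ])
  expect_equal(q1["a", ], 2 ^ (-dcq))
})

test_that("relative quantities demand an efficiency for every gene", {
  cqm <- matrix(20, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(relative_quantities(cqm, c(a = 100)), "b")
  expect_error(relative_quantities(cqm, c(a = 100, b = -100)), "-100")
})

test_that("efficiency_table fits every gene of a long dilution table", {
  dil <- rbind(simulate_dilution_series(100, gene = "g1", seed = 1),
               simulate_dilution_series(92.8, gene = "g2", seed = 2))
  tab <- efficiency_table(dil)
  expect_equal(tab$gene, c("g1", "g2"))
  expect_equal(tab$efficiency_pct, c(100, 92.8), tolerance = 1e-9)
  expect_error(fit_efficiency(dil), "one gene")
})
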