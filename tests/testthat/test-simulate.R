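test_that("simulators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_mirnas = 40)
  a <- simulate_counts(cfg, seed = 7)
  b <- simulate_counts(cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$counts, simulate_counts(cfg, seed = 8)$counts))

  q <- matrix(c(1, 0.5, 2, 1), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_identical(simulate_cq_panel(q, technical_sd = 0.2, seed = 3),
                   simulate_cq_panel(q, technical_sd = 0.2, seed = 3))
  expect_identical(simulate_dilution_series(95, sigma = 0.2, seed = 5),
                   simulate_dilution_series(95, sigma = 0.2, seed = 5))
})

test_that("noiseless counts are the rounded expected means and filter cleanly", {
  cfg <- simulation_config(n_mirnas = 100, dispersion = 0,
                           conditions = c("UV", "heat"))
  sim <- simulate_counts(cfg, seed = 11)
  mu <- sim$truth$base_means *
    2 ^ sim$truth$lfc[, "UV"] * sim$truth$library_factors[["UV_stress"]]
  expect_equal(unname(sim$counts[, "UV_stress"]), unname(round(mu)))

  # only rounding noise remains: stable genes pass a 1% threshold,
  # clearly regulated genes fail it
  norm <- normalize_counts(sim$counts)
  rep <- filter_stable(norm, sim$comparisons$UV, var_threshold_pct = 1,
                       min_reads = 0)
  expect_true(all(sim$truth$stable_set %in% rep$passed))
  moved <- rownames(sim$counts)[abs(sim$truth$lfc[, "UV"]) > log2(1.05)]
  expect_false(any(moved %in% rep$passed))
})

test_that("planted stable miRNAs are recovered at the 7%/500 thresholds", {
  cfg <- simulation_config()  # 200 miRNAs, 30% stable, 2% CV noise
  sens <- vapply(1:20, function(seed) {
    sim <- simulate_counts(cfg, seed = seed)
    norm <- normalize_counts(sim$counts)
    rep <- filter_stable(norm, sim$comparisons$UV)
    mean(sim$truth$stable_set %in% rep$passed)
  }, numeric(1))
  expect_gte(mean(sens), 0.95)
})

test_that("the Cq measurement model is exact at zero noise", {
  # E = 100%: halving a quantity costs exactly one cycle
  q <- matrix(c(1, 0.5), 1, 2, dimnames = list("g", c("s1", "s2")))
  panel <- simulate_cq_panel(q, efficiencies = 100, technical_sd = 0)
  cq <- collapse_replicates(panel)
  expect_equal(cq$cq[cq$sample == "s2"] - cq$cq[cq$sample == "s1"], 1)

  # round trip: quantities in, quantity ratios out, arbitrary efficiencies
  set.seed(13)
  qt <- matrix(2 ^ rnorm(12), 3, 4,
               dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  eff <- c(a = 89, b = 100, c = 119.6)
  panel <- simulate_cq_panel(qt, efficiencies = eff, technical_sd = 0)
  rq <- relative_quantities(collapse_replicates(panel), eff)
  expect_equal(rq, sweep(qt, 1, apply(qt, 1, max), "/"),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("technical noise shows up in replicate spread at the planted size", {
  q <- matrix(1, 2, 200, dimnames = list(c("g1", "g2"), sprintf("s%d", 1:200)))
  panel <- simulate_cq_panel(q, technical_sd = 0.15, n_technical = 3, seed = 17)
  spread <- collapse_replicates(panel)$cq_sd
  expect_equal(sqrt(mean(spread ^ 2)), 0.15, tolerance = 0.1)
})

test_that("dilution simulation and efficiency fitting are inverse at zero noise", {
  fit <- fit_efficiency(simulate_dilution_series(100, sigma = 0))
  expect_equal(fit$efficiency_pct, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit_efficiency(simulate_dilution_series(92.8, sigma = 0))$efficiency_pct,
               92.8, tolerance = 1e-9)
  noisy <- vapply(1:100, function(seed)
    fit_efficiency(simulate_dilution_series(100, sigma = 0.2, n_replicates = 3,
                                            seed = seed))$efficiency_pct,
    numeric(1))
  expect_true(all(abs(noisy - 100) < 10))
  expect_lt(fit_efficiency(simulate_dilution_series(100, sigma = 0.2,
                                                    seed = 1))$r_squared, 1)
})

test_that("degenerate simulator configurations are rejected", {
  expect_error(simulation_config(n_mirnas = 0), "degenerate")
  expect_error(simulation_config(stable_fraction = 1.2), "stable_fraction")
  expect_error(simulation_config(dispersion = -1), "nonnegative")
  expect_error(simulate_dilution_series(100, n_dilutions = 2), "3 dilutions")
  expect_error(simulate_cq_panel(matrix(-1, 1, 1)), "positive")
})
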