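test_that("association power behaves like a power function", {
  # null variant: power collapses to the significance level
  expect_lt(abs(association_power(1, 0.1, 1000, alpha = 5e-8) - 5e-8), 1e-9)
  expect_equal(association_power(1, 0.1, 1000, alpha = 0.05), 0.05,
               tolerance = 1e-6)
  # monotone in case count, relative risk and allele frequency
  pw_n <- vapply(c(50, 100, 229, 500, 1000),
                 function(n) association_power(3, 0.1, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  pw_rr <- vapply(c(1.5, 2, 2.5, 3, 4),
                  function(r) association_power(r, 0.1, 229), numeric(1))
  expect_true(all(diff(pw_rr) > 0))
  pw_maf <- vapply(c(0.01, 0.025, 0.05, 0.1),
                   function(m) association_power(3, m, 229), numeric(1))
  expect_true(all(diff(pw_maf) > 0))
  expect_gt(association_power(3, 0.1, 1000), 0.99)
  expect_error(association_power(0.5, 0.1, 100), "rr")
  expect_error(association_power(3, 0.7, 100), "maf")
})

test_that("minimum case counts sit exactly on the power boundary", {
  for (cell in list(c(3, 0.10), c(2, 0.05))) {
    n <- min_cases_for_power(cell[1], cell[2])
    expect_gte(association_power(cell[1], cell[2], n), 0.80)
    expect_lt(association_power(cell[1], cell[2], n - 1), 0.80)
  }
  # decreasing in rr and maf
  grid_rr <- vapply(c(2, 2.5, 3), min_cases_for_power, integer(1), maf = 0.1)
  expect_true(all(diff(grid_rr) < 0))
  grid_maf <- vapply(c(0.01, 0.05, 0.1), function(m)
    min_cases_for_power(3, m), integer(1))
  expect_true(all(diff(grid_maf) < 0))
})

test_that("variant calibration matches a genotype-simulation oracle", {
  v <- variant_sens_spec(3, 0.05)
  expect_equal(v$carrier_freq, 1 - 0.95^2)
  expect_equal(v$sensitivity, 0.2448, tolerance = 2e-4)
  expect_equal(v$specificity, 0.9077, tolerance = 2e-4)
  # brute-force oracle: simulate carriage and disease in a population
  set.seed(1234)
  n <- 1e6
  for (case in list(c(3, 0.05), c(2, 0.10), c(5, 0.01))) {
    vv <- variant_sens_spec(case[1], case[2])
    carrier <- runif(n) < vv$carrier_freq
    k <- 0.0343 / (vv$carrier_freq * case[1] + 1 - vv$carrier_freq)
    disease <- runif(n) < ifelse(carrier, case[1] * k, k)
    sens_hat <- mean(carrier[disease])
    spec_hat <- mean(!carrier[!disease])
    se_s <- sqrt(sens_hat * (1 - sens_hat) / sum(disease))
    se_p <- sqrt(spec_hat * (1 - spec_hat) / sum(!disease))
    expect_lt(abs(vv$sensitivity - sens_hat), 3 * se_s)
    expect_lt(abs(vv$specificity - spec_hat), 3 * se_p)
  }
  # an uninformative variant reduces to carrier frequency
  v1 <- variant_sens_spec(1, 0.05)
  expect_equal(v1$sensitivity, v1$carrier_freq, tolerance = 1e-12)
  expect_equal(v1$specificity, 1 - v1$carrier_freq, tolerance = 1e-12)
})

test_that("scenario engine augments the panel and re-runs the economics", {
  p <- model_parameters()
  sc <- scenario_cea(p, rr = 3, maf = 0.05, n_iter = 2000, seed = 11)
  expect_equal(sc$panel$sensitivity,
               combine_sensitivity(c(0.430, sc$variant$sensitivity)),
               tolerance = 2e-3)
  base_icer <- compare_strategies(p, panel_combined())$icer
  expect_lt(sc$deterministic$icer, base_icer)
  # an uninformative variant only changes the test cost
  sc1 <- scenario_cea(p, rr = 1, maf = 1e-9, test_cost = 110, n_iter = 10,
                      seed = 1)
  expect_equal(sc1$deterministic$icer, base_icer, tolerance = 1e-6)
})

test_that("the power/ICER grid reproduces the published orderings", {
  grid <- table2_grid()
  expect_identical(nrow(grid), 15L)
  base_icer <- compare_strategies(model_parameters(), panel_combined())$icer
  for (r in unique(grid$rr)) {
    row <- grid[grid$rr == r, ]
    row <- row[order(-row$maf), ]
    expect_true(all(diff(row$min_cases) > 0))   # cases rise as MAF falls
    expect_true(all(diff(row$icer) > 0))        # ICER rises as MAF falls
  }
  for (m in unique(grid$maf)) {
    col <- grid[grid$maf == m, ]
    col <- col[order(-col$rr), ]
    expect_true(all(diff(col$min_cases) > 0))   # cases rise as RR falls
  }
  expect_true(all(grid$icer[grid$maf > 0.025] < base_icer))
})
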