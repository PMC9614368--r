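test_that("patient trajectories honour the model's degenerate limits", {
  p <- model_parameters()
  # no prevalence: everyone completes the horizon on clozapine
  pts <- simulate_patients(model_parameters(ciag_prevalence = 0),
                           "standard_of_care", n = 200, seed = 1)
  expect_true(all(is.na(pts$ciag_cycle)))
  expect_equal(stats::sd(pts$cost), 0)
  # perfect test and perfect prevention: PGx arm sees no events
  perfect <- simulate_patients(
    model_parameters(prevention_rate = 1), "pgx_guided",
    panel_performance(sensitivity = 1, specificity = 0.5), n = 2000, seed = 2)
  expect_true(all(is.na(perfect$ciag_cycle)))
  # a fixed seed reproduces a single trajectory exactly
  one <- simulate_patients(p, "pgx_guided", n = 1, seed = 99)
  expect_identical(one, simulate_patients(p, "pgx_guided", n = 1, seed = 99))
  # events only occur within the onset window, to destined patients
  pts <- simulate_patients(model_parameters(ciag_prevalence = 0.5),
                           "standard_of_care", n = 5000, seed = 3)
  expect_true(all(pts$ciag_cycle[!is.na(pts$ciag_cycle)] <=
                    p$ciag_risk_window_cycles))
  expect_true(all(pts$destined[!is.na(pts$ciag_cycle)]))
})

test_that("test results track sensitivity and specificity", {
  p <- model_parameters()
  pts <- simulate_patients(model_parameters(ciag_prevalence = 0.3),
                           "pgx_guided", panel_combined(), n = 60000, seed = 4)
  pos_destined <- mean(pts$test_positive[pts$destined])
  pos_clear <- mean(pts$test_positive[!pts$destined])
  n_d <- sum(pts$destined)
  expect_lt(abs(pos_destined - 0.43), 3 * sqrt(0.43 * 0.57 / n_d) + 2e-3)
  expect_lt(abs(pos_clear - (1 - 0.869)),
            3 * sqrt(0.869 * 0.131 / (nrow(pts) - n_d)) + 2e-3)
  # standard of care never averts
  soc <- simulate_patients(p, "standard_of_care", n = 1000, seed = 5)
  expect_false(any(soc$averted))
})

test_that("microsimulation means converge to the cohort expectations", {
  p <- model_parameters()
  for (arm in c("standard_of_care", "pgx_guided")) {
    strat <- if (arm == "pgx_guided") strategy(arm, panel_combined())
             else strategy(arm)
    cohort <- run_cohort(p, strat)
    for (n in c(20000, 80000)) {
      ms <- simulate_cohort(p, arm, n = n, seed = 31)
      expect_lt(abs(ms$mean_cost - cohort$discounted_cost), 3 * ms$se_cost,
                label = sprintf("%s cost at n=%d", arm, n))
      expect_lt(abs(ms$mean_qaly - cohort$discounted_qaly), 3 * ms$se_qaly,
                label = sprintf("%s qaly at n=%d", arm, n))
    }
  }
})

test_that("simulated CIAG fraction matches the cumulative incidence", {
  p <- model_parameters()
  ms <- simulate_cohort(p, "standard_of_care", n = 100000, seed = 6)
  se <- sqrt(0.0343 * (1 - 0.0343) / 100000)
  expect_lt(abs(ms$ciag_fraction - 0.0343), 3 * se)
  # arm differences come only from the test cost and prevention
  p0 <- model_parameters(prevention_rate = 0, cost_genetic_test = 0)
  a <- simulate_cohort(p0, "standard_of_care", n = 50000, seed = 8)
  b <- simulate_cohort(p0, "pgx_guided", n = 50000, seed = 8)
  expect_lt(abs(a$mean_cost - b$mean_cost),
            3 * sqrt(a$se_cost^2 + b$se_cost^2))
  expect_lt(abs(a$mean_qaly - b$mean_qaly),
            3 * sqrt(a$se_qaly^2 + b$se_qaly^2))
})

test_that("the shipped synthetic patient table regenerates exactly", {
  fixture <- system.file("extdata", "synthetic_patients_n1000_seed7.csv",
                         package = "clozapgx")
  expect_true(nzchar(fixture))
  ref <- read.csv(fixture)
  pts <- simulate_patients(model_parameters(), "pgx_guided",
                           panel_combined(), n = 1000, seed = 7)
  pts$cost <- round(pts$cost, 2)
  pts$qaly <- round(pts$qaly, 6)
  expect_equal(nrow(ref), 1000L)
  expect_equal(ref$destined, pts$destined)
  expect_equal(ref$ciag_cycle, pts$ciag_cycle)
  expect_equal(ref$cost, pts$cost, tolerance = 1e-9)
  expect_equal(ref$qaly, pts$qaly, tolerance = 1e-9)
})
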