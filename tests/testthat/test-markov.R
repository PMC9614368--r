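test_that("per-cycle hazard inverts the cumulative incidence", {
  for (case in list(c(0.0343, 5), c(0.0343, 36), c(0.3, 12), c(0.0299, 5))) {
    h <- ciag_monthly_hazard(case[1], case[2])
    expect_equal(1 - (1 - h)^case[2], case[1], tolerance = 1e-12)
    # independent root-finding oracle
    root <- uniroot(function(x) 1 - (1 - x)^case[2] - case[1],
                    c(0, 0.999), tol = 1e-14)$root
    expect_equal(h, root, tolerance = 1e-9)
  }
  expect_equal(ciag_monthly_hazard(0, 7), 0)
  expect_error(ciag_monthly_hazard(1, 5), "\\[0, 1\\)")
})

test_that("cohort trace conserves mass, absorbs and hits the target incidence", {
  p <- model_parameters()
  for (strat in list(strategy("standard_of_care"),
                     strategy("pgx_guided", panel_combined()))) {
    res <- run_cohort(p, strat)
    tr <- res$trace
    occ <- tr$on_clz_at_risk + tr$on_clz_safe + tr$on_substitute
    expect_true(all(abs(occ - 1) < 1e-10))
    expect_true(all(diff(tr$on_substitute) >= -1e-15)) # absorbing state
    target <- if (strat$name == "pgx_guided") {
      effective_ciag_incidence(p$ciag_prevalence,
                               panel_combined()$sensitivity,
                               p$prevention_rate)
    } else {
      p$ciag_prevalence
    }
    expect_equal(res$cumulative_incidence, target, tolerance = 1e-10)
    expect_equal(sum(tr$incident_ciag), res$cumulative_incidence,
                 tolerance = 1e-12)
    # no one remains at risk after the window closes
    expect_true(all(tr$on_clz_at_risk[tr$cycle > p$ciag_risk_window_cycles] == 0))
  }
})

test_that("a CIAG-free cohort accrues the closed-form discounted annuity", {
  p <- model_parameters(ciag_prevalence = 0)
  res <- run_cohort(p, strategy("standard_of_care"))
  expected_qaly <- (0.693 / 12) * sum(1.035^(-(1:120) / 12))
  expect_equal(res$discounted_qaly, expected_qaly, tolerance = 1e-12)
  expect_equal(expected_qaly, 5.85529, tolerance = 1e-5)
  expected_cost <- (1.23 * 365.25 / 12 + 10.6) * sum(1.035^(-(1:120) / 12))
  expect_equal(res$discounted_cost, expected_cost, tolerance = 1e-10)
  # discounting strictly reduces QALYs
  p0 <- model_parameters(ciag_prevalence = 0, discount_rate_annual = 0)
  expect_lt(res$discounted_qaly,
            run_cohort(p0, strategy("standard_of_care"))$discounted_qaly)
})

test_that("cohort engine matches an independent transition-matrix oracle", {
  cases <- list(
    model_parameters(),
    model_parameters(ciag_risk_window_cycles = 5),
    model_parameters(ciag_prevalence = 0.2, prevention_rate = 0.5,
                     ciag_risk_window_cycles = 120),
    model_parameters(discount_rate_annual = 0, horizon_years = 2,
                     ciag_risk_window_cycles = 6)
  )
  for (p in cases) {
    soc <- run_cohort(p, strategy("standard_of_care"))
    ref <- reference_cohort(p, p$ciag_prevalence, 0)
    expect_equal(soc$discounted_cost, ref$cost, tolerance = 1e-10)
    expect_equal(soc$discounted_qaly, ref$qaly, tolerance = 1e-10)
    pgx <- run_cohort(p, strategy("pgx_guided", panel_combined()))
    inc <- effective_ciag_incidence(p$ciag_prevalence,
                                    panel_combined()$sensitivity,
                                    p$prevention_rate)
    ref <- reference_cohort(p, inc, p$cost_genetic_test)
    expect_equal(pgx$discounted_cost, ref$cost, tolerance = 1e-10)
    expect_equal(pgx$discounted_qaly, ref$qaly, tolerance = 1e-10)
  }
})

test_that("closed-form arm values agree with the cycle-loop engine", {
  p <- model_parameters()
  v <- (1 + p$discount_rate_annual)^(-1 / 12)
  for (inc in c(0, 0.0343, 0.0298753, 0.4)) {
    h <- if (inc == 0) 0 else ciag_monthly_hazard(inc, p$ciag_risk_window_cycles)
    cf <- clozapgx:::.arm_values(
      h, 110, 1.23 * p$days_per_cycle + 10.6, 5.11 * p$days_per_cycle,
      469.48, 0.693 / 12, 0.560 / 12, p$n_cycles,
      p$ciag_risk_window_cycles, v)
    ref <- reference_cohort(p, inc, 110)
    expect_equal(cf$cost, ref$cost, tolerance = 1e-9)
    expect_equal(cf$qaly, ref$qaly, tolerance = 1e-9)
  }
})

test_that("strategy comparison yields the expected incremental structure", {
  p <- model_parameters()
  ce <- compare_strategies(p, panel_combined())
  expect_gt(ce$delta_qaly, 0)
  expect_gt(ce$delta_cost, 0)
  expect_identical(ce$icer_flag, "icer")
  expect_lt(ce$icer, 30000)
  # coinciding strategies: no prevention benefit, free test
  p_null <- model_parameters(prevention_rate = 0, cost_genetic_test = 0)
  ce0 <- compare_strategies(p_null, panel_combined())
  expect_equal(ce0$delta_cost, 0, tolerance = 1e-12)
  expect_equal(ce0$delta_qaly, 0, tolerance = 1e-15)
  expect_identical(ce0$icer_flag, "undefined")
  # a free test with real prevention dominates
  ce_free <- compare_strategies(model_parameters(cost_genetic_test = 0),
                                panel_combined())
  expect_identical(ce_free$icer_flag, "dominant")
  expect_lt(ce_free$delta_cost, 0)
})

test_that("ICER falls with sensitivity and ignores specificity", {
  p <- model_parameters()
  dsa_sens <- one_way_dsa(p, panel_combined(), "sensitivity",
                          seq(0.2, 0.8, by = 0.1))
  expect_true(all(diff(dsa_sens$icer) < 0))
  dsa_spec <- one_way_dsa(p, panel_combined(), "specificity",
                          seq(0.7, 0.99, length.out = 7))
  expect_lt(max(dsa_spec$icer) - min(dsa_spec$icer), 1e-9)
  # single-point grid at the panel's own value returns the base case
  base <- compare_strategies(p, panel_combined())$icer
  expect_equal(one_way_dsa(p, panel_combined(), "sensitivity",
                           panel_combined()$sensitivity)$icer,
               base, tolerance = 1e-12)
  expect_error(one_way_dsa(p, panel_combined(), "nope", 1:2), "unknown")
  expect_error(one_way_dsa(p, panel_combined(), "sensitivity", c(0.5, 0.4)),
               "increasing")
})

test_that("PGx benefit is monotone: more QALYs whenever prevention helps", {
  for (pr in c(0, 0.1, 0.3, 0.9)) {
    p <- model_parameters(prevention_rate = pr)
    ce <- compare_strategies(p, panel_combined())
    expect_gte(ce$delta_qaly, 0)
  }
})
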