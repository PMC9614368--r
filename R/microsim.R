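#' Simulate individual patient trajectories
#'
#' Individual-level counterpart of the cohort model, used as a brute-force
#' oracle for [run_cohort()] and as a synthetic-data generator. Each patient
#' draws: destined-for-CIAG status at the cohort prevalence; a test result
#' (positive with probability `sensitivity` if destined, `1 - specificity`
#' otherwise); in the PGx arm, aversion of the event with probability
#' `prevention_rate` for destined test-positives; and, for destined
#' non-averted patients, an onset cycle from the same truncated-geometric
#' per-cycle hazard the cohort engine uses. Per-cycle rewards and
#' discounting are identical to the cohort engine's per-state rules, so
#' microsimulation means converge to the cohort expectations by the law of
#' large numbers.
#'
#' @param params A [model_parameters()] object.
#' @param arm `"pgx_guided"` or `"standard_of_care"`.
#' @param panel Screening panel (used for the test result in both arms; in
#'   the standard-of-care arm the result is recorded but has no effect and
#'   no cost).
#' @param n Number of patients.
#' @param seed Integer RNG seed.
#' @return A data frame with columns `patient_id`, `destined`,
#'   `test_positive`, `averted`, `ciag_cycle` (`NA` when no event), `cost`,
#'   `qaly`.
#' @examples
#' head(simulate_patients(model_parameters(), "pgx_guided", n = 10, seed = 7))
#' @export
simulate_patients <- function(params, arm = c("pgx_guided", "standard_of_care"),
                              panel = panel_combined(), n = 1000, seed = 1) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "clz_params"), inherits(panel, "clz_panel"),
            n >= 1)
  set.seed(seed)
  prev <- params$ciag_prevalence
  destined <- runif(n) < prev
  test_positive <- ifelse(destined,
                          runif(n) < panel$sensitivity,
                          runif(n) < 1 - panel$specificity)
  averted <- destined & test_positive & (arm == "pgx_guided") &
    (runif(n) < params$prevention_rate)
  has_event <- destined & !averted

  N <- params$n_cycles
  w <- params$ciag_risk_window_cycles
  inc <- if (arm == "pgx_guided") {
    effective_ciag_incidence(prev, panel$sensitivity, params$prevention_rate)
  } else {
    prev
  }
  h <- ciag_monthly_hazard(inc, w)
  ciag_cycle <- rep(NA_integer_, n)
  if (any(has_event)) {
    # conditional onset-cycle pmf matching the cohort trace exactly
    pmf <- h * (1 - h)^(0:(w - 1L))
    ciag_cycle[has_event] <- sample.int(w, sum(has_event), replace = TRUE,
                                        prob = pmf / sum(pmf))
  }

  disc <- .discount_factors(params)
  P <- c(0, cumsum(disc))               # P[m + 1] = sum_{t<=m} v^t
  A <- P[N + 1L]
  rw <- .cycle_rewards(params)
  test_cost <- if (arm == "pgx_guided") params$cost_genetic_test else 0

  tau <- ciag_cycle
  idx <- ifelse(is.na(tau), N + 1L, tau)
  pre <- P[idx]                         # discounted cycles spent on clozapine
  ev_disc <- ifelse(is.na(tau), 0, disc[idx])
  cost <- test_cost + rw$c_clz * pre + rw$c_sub * (A - pre) +
    params$cost_ciag_treatment * ev_disc
  qaly <- rw$u_clz * pre + rw$u_sub * (A - pre)

  data.frame(patient_id = seq_len(n), destined = destined,
             test_positive = test_positive, averted = averted,
             ciag_cycle = ciag_cycle, cost = cost, qaly = qaly)
}

#' Monte Carlo cohort means from the microsimulation
#'
#' @inheritParams simulate_patients
#' @return List with `n`, per-patient `mean_cost`, `mean_qaly`, their
#'   standard errors, and the simulated CIAG fraction.
#' @examples
#' simulate_cohort(model_parameters(), "standard_of_care", n = 5000, seed = 1)
#' @export
simulate_cohort <- function(params, arm = c("pgx_guided", "standard_of_care"),
                            panel = panel_combined(), n = 200000, seed = 1) {
  pts <- simulate_patients(params, arm, panel, n = n, seed = seed)
  list(n = n,
       mean_cost = mean(pts$cost),
       se_cost = stats::sd(pts$cost) / sqrt(n),
       mean_qaly = mean(pts$qaly),
       se_qaly = stats::sd(pts$qaly) / sqrt(n),
       ciag_fraction = mean(!is.na(pts$ciag_cycle)))
}
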