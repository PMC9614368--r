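#' Per-cycle CIAG hazard from a cumulative incidence
#'
#' Solves `1 - (1 - h)^window = cumulative_incidence` for the constant
#' per-cycle transition probability applied inside the onset window (zero
#' after).
#'
#' @param cumulative_incidence Cumulative CIAG probability in \[0, 1).
#' @param window_cycles Number of cycles over which onset is distributed.
#' @return The per-cycle hazard `h` (vectorised over
#'   `cumulative_incidence`).
#' @examples
#' ciag_monthly_hazard(0.0343, 5) # 0.0069596
#' @export
ciag_monthly_hazard <- function(cumulative_incidence, window_cycles) {
  if (any(cumulative_incidence < 0 | cumulative_incidence >= 1))
    stop("`cumulative_incidence` must be in [0, 1)", call. = FALSE)
  if (window_cycles < 1) stop("`window_cycles` must be >= 1", call. = FALSE)
  1 - (1 - cumulative_incidence)^(1 / window_cycles)
}

#' Define a treatment strategy
#'
#' @param name `"standard_of_care"` (no genetic testing) or `"pgx_guided"`
#'   (universal pre-emptive genotyping; flagged destined patients have a
#'   `prevention_rate` chance of averting CIAG).
#' @param panel A [panel_performance()] object; required for the PGx arm.
#' @return A `clz_strategy`.
#' @export
strategy <- function(name = c("standard_of_care", "pgx_guided"),
                     panel = NULL) {
  name <- match.arg(name)
  if (name == "pgx_guided" && !inherits(panel, "clz_panel"))
    stop("the PGx-guided strategy requires a `panel`", call. = FALSE)
  structure(list(name = name, panel = panel,
                 test_cost_applied = name == "pgx_guided"),
            class = "clz_strategy")
}

# Per-cycle reward constants for a parameter set (all GBP or utility/cycle).
.cycle_rewards <- function(p) {
  list(
    c_clz = p$cost_clz_per_day * p$days_per_cycle + p$cost_blood_test_per_month,
    c_sub = p$cost_substitute_per_day * p$days_per_cycle,
    u_clz = p$utility_clz * p$cycle_length_months / 12,
    u_sub = p$utility_substitute * p$cycle_length_months / 12
  )
}

# Per-cycle discount factors (1 + r)^(-t * cycle_months / 12), t = 1..N.
.discount_factors <- function(p) {
  t <- seq_len(p$n_cycles)
  (1 + p$discount_rate_annual)^(-t * p$cycle_length_months / 12)
}

#' Run the Markov cohort model for one strategy
#'
#' The cohort starts fully on clozapine and at risk of CIAG. During the
#' onset window a constant per-cycle hazard moves incident cases to the
#' absorbing substitute-treatment state (with the one-off CIAG treatment
#' cost charged at the transition cycle, which already accrues the
#' destination state's rewards); after the window the remaining clozapine
#' mass becomes safe. Clozapine states accrue drug plus monitoring costs and
#' the clozapine utility; the substitute state accrues substitute drug costs
#' and the lower substitute utility. The PGx arm additionally pays the
#' genetic-test cost up front (undiscounted) and replaces the raw prevalence
#' with [effective_ciag_incidence()]. All cycle rewards are discounted by
#' `(1 + r)^(-t/12)` at cycle `t` (end-of-cycle convention).
#'
#' @param params A [model_parameters()] object.
#' @param strat A [strategy()] object.
#' @return A `clz_strategy_result`: list with `discounted_cost`,
#'   `discounted_qaly`, `cumulative_incidence` and the cohort `trace` (a
#'   data frame over cycles 0..N with state occupancies and the incident
#'   CIAG fraction).
#' @examples
#' res <- run_cohort(model_parameters(), strategy("standard_of_care"))
#' tail(res$trace$on_substitute, 1) # 0.0343
#' @export
run_cohort <- function(params, strat) {
  stopifnot(inherits(params, "clz_params"), inherits(strat, "clz_strategy"))
  inc <- if (strat$name == "pgx_guided") {
    effective_ciag_incidence(params$ciag_prevalence,
                             strat$panel$sensitivity,
                             params$prevention_rate)
  } else {
    params$ciag_prevalence
  }
  N <- params$n_cycles
  w <- params$ciag_risk_window_cycles
  h <- ciag_monthly_hazard(inc, w)
  rw <- .cycle_rewards(params)
  disc <- .discount_factors(params)

  at_risk <- numeric(N + 1L); safe <- numeric(N + 1L); sub <- numeric(N + 1L)
  incident <- numeric(N + 1L)
  at_risk[1L] <- 1
  for (t in seq_len(N)) {
    i <- t + 1L
    if (t <= w) {
      incident[i] <- at_risk[i - 1L] * h
      at_risk[i] <- at_risk[i - 1L] * (1 - h)
      safe[i] <- safe[i - 1L]
      if (t == w) { # window closes: remaining at-risk mass is safe
        safe[i] <- safe[i] + at_risk[i]
        at_risk[i] <- 0
      }
    } else {
      at_risk[i] <- at_risk[i - 1L]
      safe[i] <- safe[i - 1L]
    }
    sub[i] <- sub[i - 1L] + incident[i]
  }
  on_clz <- at_risk + safe
  cost <- sum(disc * (on_clz[-1L] * rw$c_clz + sub[-1L] * rw$c_sub +
                        incident[-1L] * params$cost_ciag_treatment))
  if (strat$test_cost_applied) cost <- cost + params$cost_genetic_test
  qaly <- sum(disc * (on_clz[-1L] * rw$u_clz + sub[-1L] * rw$u_sub))

  trace <- data.frame(cycle = 0:N, on_clz_at_risk = at_risk,
                      on_clz_safe = safe, on_substitute = sub,
                      incident_ciag = incident)
  structure(list(strategy = strat$name,
                 discounted_cost = cost,
                 discounted_qaly = qaly,
                 cumulative_incidence = sub[N + 1L],
                 trace = trace),
            class = "clz_strategy_result")
}

#' @export
print.clz_strategy_result <- function(x, ...) {
  cat(sprintf("<clz_strategy_result> %s: cost %.2f GBP, %.5f QALYs, CIAG %.4f\n",
              x$strategy, x$discounted_cost, x$discounted_qaly,
              x$cumulative_incidence))
  invisible(x)
}

# Closed-form discounted arm values, vectorised over parameter draws.
# Identical model to run_cohort (geometric sums replace the cycle loop);
# the testthat suite asserts equality to 1e-9.
.arm_values <- function(h, test_cost, c_clz, c_sub, c_event, u_clz_cycle,
                        u_sub_cycle, n_cycles, window, v) {
  t_all <- seq_len(n_cycles)
  A <- sum(v^t_all)                       # sum_t v^t
  A_tail <- if (window < n_cycles) sum(v^((window + 1L):n_cycles)) else 0
  x <- v * (1 - h)
  g1 <- x * (1 - x^window) / (1 - x)      # sum_{t<=w} (v(1-h))^t
  G <- g1 + (1 - h)^window * A_tail       # sum_t v^t * P(still on CLZ at t)
  E <- ifelse(h == 0, 0, h / (1 - h) * g1) # sum_t v^t * incident fraction
  cost <- test_cost + c_clz * G + c_sub * (A - G) + c_event * E
  qaly <- u_clz_cycle * G + u_sub_cycle * (A - G)
  list(cost = cost, qaly = qaly)
}

#' Compare the PGx-guided strategy with standard of care
#'
#' Runs both arms on identical parameters and returns incremental cost,
#' incremental QALYs and the incremental cost-effectiveness ratio
#' ICER = (Cost_PGx - Cost_SoC) / (QALY_PGx - QALY_SoC).
#'
#' @param params A [model_parameters()] object.
#' @param panel A [panel_performance()] object for the PGx arm.
#' @return A `clz_ce` with both `clz_strategy_result`s, `delta_cost`,
#'   `delta_qaly`, `icer` (GBP/QALY, `NA` when flagged) and `icer_flag`
#'   (`"icer"`, `"dominant"`, `"dominated"` or `"undefined"`).
#' @examples
#' ce <- compare_strategies(model_parameters(), panel_combined())
#' ce$icer
#' @export
compare_strategies <- function(params, panel = panel_combined()) {
  soc <- run_cohort(params, strategy("standard_of_care"))
  pgx <- run_cohort(params, strategy("pgx_guided", panel))
  dc <- pgx$discounted_cost - soc$discounted_cost
  dq <- pgx$discounted_qaly - soc$discounted_qaly
  if (abs(dq) < 1e-300) {
    icer <- NA_real_
    flag <- "undefined"
  } else if (dq > 0 && dc <= 0) {
    icer <- NA_real_
    flag <- "dominant"
  } else if (dq < 0 && dc >= 0) {
    icer <- NA_real_
    flag <- "dominated"
  } else {
    icer <- dc / dq
    flag <- "icer"
  }
  structure(list(soc = soc, pgx = pgx, delta_cost = dc, delta_qaly = dq,
                 icer = icer, icer_flag = flag, panel = panel),
            class = "clz_ce")
}

#' @export
print.clz_ce <- function(x, ...) {
  cat("<clz_ce> PGx-guided vs standard of care\n")
  cat(sprintf("  SoC: cost %.2f, QALY %.5f | PGx: cost %.2f, QALY %.5f\n",
              x$soc$discounted_cost, x$soc$discounted_qaly,
              x$pgx$discounted_cost, x$pgx$discounted_qaly))
  cat(sprintf("  delta cost %.2f GBP, delta QALY %.6f, %s\n",
              x$delta_cost, x$delta_qaly,
              if (x$icer_flag == "icer") sprintf("ICER %.2f GBP/QALY", x$icer)
              else x$icer_flag))
  invisible(x)
}
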