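#' Sample parameter vectors for probabilistic sensitivity analysis
#'
#' Draws `n_iter` independent parameter vectors from the registry's
#' distributions: gamma for costs, beta for utilities, the prevention rate
#' and panel performance; parameters flagged fixed are constant across
#' draws. Draws are materialised up-front from a single master seed in fixed
#' column order, so results are bitwise reproducible.
#'
#' @param registry A [default_registry()] object.
#' @param n_iter Number of draws.
#' @param seed Integer RNG seed.
#' @return A data frame with `n_iter` rows, one column per registry entry.
#' @export
sample_parameters <- function(registry, n_iter, seed) {
  stopifnot(inherits(registry, "clz_registry"), n_iter >= 1)
  set.seed(seed)
  draws <- lapply(registry, function(e) {
    d <- e$dist
    switch(d$kind,
      gamma = rgamma(n_iter, shape = d$param_a, rate = d$param_b),
      beta  = rbeta(n_iter, d$param_a, d$param_b),
      fixed = rep(d$value, n_iter)
    )
  })
  as.data.frame(draws)
}

#' Run the probabilistic sensitivity analysis
#'
#' Evaluates the two-strategy comparison at every sampled parameter vector
#' using the closed-form cohort engine (algebraically identical to
#' [run_cohort()], vectorised over draws).
#'
#' @param params A [model_parameters()] object (structural settings and the
#'   fixed parameters).
#' @param panel The screening panel of the PGx arm.
#' @param n_iter Number of Monte Carlo iterations (the reference analysis
#'   uses 100,000).
#' @param seed Integer RNG seed.
#' @param sample_panel If `TRUE` the panel sensitivity/specificity are drawn
#'   from their registry distributions; if `FALSE` they are held at the
#'   panel's point values (used for panels without published uncertainty
#'   distributions, e.g. the HLA-only comparison or calibrated scenario
#'   panels).
#' @param registry Parameter registry; defaults to
#'   `default_registry(params, panel)`.
#' @return A `clz_psa`: list with `draws` (sampled parameters) and `results`
#'   (per-iteration discounted cost and QALY per strategy plus increments),
#'   and the call settings.
#' @examples
#' psa <- run_psa(model_parameters(), panel_combined(), n_iter = 1000, seed = 1)
#' summary(psa)
#' @export
run_psa <- function(params, panel = panel_combined(), n_iter = 100000,
                    seed = 1, sample_panel = TRUE,
                    registry = default_registry(params, panel)) {
  stopifnot(inherits(params, "clz_params"), inherits(panel, "clz_panel"))
  if (!sample_panel) {
    registry$sensitivity <- list(
      mean = panel$sensitivity,
      dist = dist_spec("fixed", value = panel$sensitivity), psa = FALSE)
    registry$specificity <- list(
      mean = panel$specificity,
      dist = dist_spec("fixed", value = panel$specificity), psa = FALSE)
  }
  draws <- sample_parameters(registry, n_iter, seed)

  v <- (1 + params$discount_rate_annual)^(-params$cycle_length_months / 12)
  cyc_yr <- params$cycle_length_months / 12
  c_clz <- draws$cost_clz_per_day * params$days_per_cycle +
    draws$cost_blood_test_per_month
  c_sub <- draws$cost_substitute_per_day * params$days_per_cycle
  w <- params$ciag_risk_window_cycles

  h_soc <- ciag_monthly_hazard(draws$ciag_prevalence, w)
  inc_pgx <- effective_ciag_incidence(draws$ciag_prevalence,
                                      draws$sensitivity,
                                      draws$prevention_rate)
  h_pgx <- ciag_monthly_hazard(inc_pgx, w)

  soc <- .arm_values(h_soc, 0, c_clz, c_sub, draws$cost_ciag_treatment,
                     draws$utility_clz * cyc_yr,
                     draws$utility_substitute * cyc_yr,
                     params$n_cycles, w, v)
  pgx <- .arm_values(h_pgx, draws$cost_genetic_test, c_clz, c_sub,
                     draws$cost_ciag_treatment,
                     draws$utility_clz * cyc_yr,
                     draws$utility_substitute * cyc_yr,
                     params$n_cycles, w, v)

  results <- data.frame(
    iter = seq_len(n_iter),
    cost_soc = soc$cost, qaly_soc = soc$qaly,
    cost_pgx = pgx$cost, qaly_pgx = pgx$qaly,
    delta_cost = pgx$cost - soc$cost,
    delta_qaly = pgx$qaly - soc$qaly
  )
  structure(list(draws = draws, results = results, n_iter = n_iter,
                 seed = seed, panel = panel, sample_panel = sample_panel,
                 params = params),
            class = "clz_psa")
}

#' @export
print.clz_psa <- function(x, ...) {
  cat(sprintf("<clz_psa> %d iterations (seed %d), panel sens %.3f / spec %.3f (%s)\n",
              x$n_iter, x$seed, x$panel$sensitivity, x$panel$specificity,
              if (x$sample_panel) "sampled" else "fixed"))
  invisible(x)
}

#' @describeIn run_psa Monte Carlo summary: arm means, incremental means,
#'   ICER computed from mean increments, mean/median of per-draw ICERs and
#'   the probability of cost-effectiveness at `wtp`.
#' @param object A `clz_psa`.
#' @param wtp Willingness-to-pay threshold (GBP/QALY) for the
#'   cost-effectiveness probability.
#' @param ... Unused.
#' @export
summary.clz_psa <- function(object, wtp = 30000, ...) {
  r <- object$results
  ratio <- r$delta_cost / r$delta_qaly
  ok <- r$delta_qaly > 0 & r$delta_cost > 0
  list(
    n_iter = object$n_iter,
    mean_cost_soc = mean(r$cost_soc), mean_qaly_soc = mean(r$qaly_soc),
    mean_cost_pgx = mean(r$cost_pgx), mean_qaly_pgx = mean(r$qaly_pgx),
    mean_delta_cost = mean(r$delta_cost),
    mean_delta_qaly = mean(r$delta_qaly),
    icer_of_means = mean(r$delta_cost) / mean(r$delta_qaly),
    mean_icer = mean(ratio[ok]), median_icer = stats::median(ratio[ok]),
    wtp = wtp,
    p_cost_effective = mean(wtp * r$delta_qaly - r$delta_cost > 0)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the fraction of PSA draws with positive
#' incremental net monetary benefit, `wtp * delta_qaly - delta_cost > 0`.
#'
#' @param psa A `clz_psa` object.
#' @param wtp_grid Vector of willingness-to-pay values (GBP/QALY).
#' @return A data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 500)) {
  stopifnot(inherits(psa, "clz_psa"))
  if (!length(wtp_grid)) stop("`wtp_grid` must be non-empty", call. = FALSE)
  dq <- psa$results$delta_qaly
  dc <- psa$results$delta_cost
  prob <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Incremental cost-effectiveness plane quadrant fractions
#'
#' @param psa A `clz_psa` object.
#' @return Named list of draw fractions in the four quadrants (NE: more
#'   costly/more effective, SE: cheaper/more effective, etc.), summing to 1.
#' @export
ce_plane_quadrants <- function(psa) {
  r <- psa$results
  list(ne = mean(r$delta_qaly >= 0 & r$delta_cost >= 0),
       se = mean(r$delta_qaly >= 0 & r$delta_cost < 0),
       nw = mean(r$delta_qaly < 0 & r$delta_cost >= 0),
       sw = mean(r$delta_qaly < 0 & r$delta_cost < 0))
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the deterministic comparison over a grid of values for a
#' single parameter, all other parameters held at their point estimates.
#' `parameter` may be any [model_parameters()] field or `"sensitivity"` /
#' `"specificity"` of the screening panel.
#'
#' @param params A [model_parameters()] object.
#' @param panel The PGx screening panel.
#' @param parameter Name of the parameter to vary.
#' @param values Strictly increasing numeric grid.
#' @return A `data.frame` with `parameter`, `value`, `delta_cost`,
#'   `delta_qaly`, `icer`.
#' @examples
#' one_way_dsa(model_parameters(), panel_combined(), "sensitivity",
#'             c(0.2, 0.43, 0.8))
#' @export
one_way_dsa <- function(params, panel, parameter, values) {
  stopifnot(inherits(params, "clz_params"), inherits(panel, "clz_panel"))
  if (is.unsorted(values, strictly = TRUE))
    stop("`values` must be strictly increasing", call. = FALSE)
  known <- c(setdiff(names(params), "n_cycles"), "sensitivity", "specificity")
  if (!parameter %in% known)
    stop("unknown parameter: ", parameter, call. = FALSE)
  rows <- lapply(values, function(val) {
    p <- params; pl <- panel
    if (parameter %in% c("sensitivity", "specificity")) {
      pl <- panel_performance(
        sensitivity = if (parameter == "sensitivity") val else panel$sensitivity,
        specificity = if (parameter == "specificity") val else panel$specificity)
    } else {
      p <- unclass(p); p$n_cycles <- NULL; p[[parameter]] <- val
      p <- do.call(model_parameters, p)
    }
    ce <- compare_strategies(p, pl)
    data.frame(parameter = parameter, value = val,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               icer = ce$icer)
  })
  do.call(rbind, rows)
}
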