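# Genotype-class frequencies in cases and controls under Hardy-Weinberg
# equilibrium, a penetrance model and an overall disease prevalence.
.genotype_freqs <- function(rr, maf, prevalence, model) {
  p <- maf; q <- 1 - p
  g <- c(q^2, 2 * p * q, p^2) # copies of the risk allele: 0, 1, 2
  r <- switch(model,
    dominant       = c(1, rr, rr),
    recessive      = c(1, 1, rr),
    multiplicative = c(1, rr, rr^2),
    additive       = c(1, rr, 2 * rr - 1)
  )
  k <- prevalence / sum(g * r) # baseline (non-carrier) risk
  if (max(r) * k > 1)
    stop("inconsistent parameters: implied genotype risk exceeds 1",
         call. = FALSE)
  list(case = g * r * k / prevalence, ctrl = g * (1 - r * k) / (1 - prevalence),
       baseline_risk = k)
}

#' Power of a case-control genetic association test
#'
#' Power of a 1-df chi-square comparison between cases and controls, with
#' the non-centrality parameter implied by the frequency difference that a
#' risk variant of the given relative risk and minor allele frequency
#' produces under Hardy-Weinberg equilibrium and the stated disease
#' prevalence. For the `"dominant"` (default) and `"recessive"` penetrance
#' models the test contrasts carrier (risk-genotype) proportions between the
#' two groups; for `"multiplicative"` and `"additive"` it contrasts allele
#' frequencies (2N chromosomes per group). Per-group variances are used in
#' the non-centrality parameter.
#'
#' The default convention -- dominant carrier model, two controls per case --
#' is the one that reproduces the published minimum-case grid of the cited
#' association-study power calculator (see the methods vignette for the
#' calibration evidence and alternatives).
#'
#' @param rr Relative risk conferred by the risk genotype (carrier RR under
#'   the dominant model); must exceed or equal 1.
#' @param maf Minor (risk) allele frequency, in (0, 0.5\].
#' @param n_cases Number of cases genotyped.
#' @param n_controls Number of controls; `NULL` (default) uses
#'   `control_ratio * n_cases`.
#' @param alpha Significance level (genome-wide 5e-8 by default).
#' @param prevalence Disease prevalence (cumulative CIAG risk 0.0343 by
#'   default).
#' @param model Penetrance model.
#' @param control_ratio Controls per case when `n_controls` is `NULL`.
#' @return Power in \[0, 1\]; equals `alpha` when `rr = 1`.
#' @examples
#' association_power(rr = 3, maf = 0.10, n_cases = 229) # about 0.8
#' @export
association_power <- function(rr, maf, n_cases, n_controls = NULL,
                              alpha = 5e-8, prevalence = 0.0343,
                              model = c("dominant", "multiplicative",
                                        "additive", "recessive"),
                              control_ratio = 2) {
  model <- match.arg(model)
  if (rr < 1) stop("`rr` must be >= 1", call. = FALSE)
  if (maf <= 0 || maf > 0.5) stop("`maf` must be in (0, 0.5]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (n_cases < 1) stop("`n_cases` must be >= 1", call. = FALSE)
  if (is.null(n_controls)) n_controls <- control_ratio * n_cases
  f <- .genotype_freqs(rr, maf, prevalence, model)
  if (model %in% c("dominant", "recessive")) {
    p1 <- sum(f$case[2:3]); p0 <- sum(f$ctrl[2:3]) # carrier proportions
    if (model == "recessive") { p1 <- f$case[3]; p0 <- f$ctrl[3] }
    m1 <- n_cases; m0 <- n_controls
  } else {
    p1 <- f$case[3] + f$case[2] / 2; p0 <- f$ctrl[3] + f$ctrl[2] / 2
    m1 <- 2 * n_cases; m0 <- 2 * n_controls # chromosomes
  }
  ncp <- (p1 - p0)^2 / (p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Minimum number of cases for a target power
#'
#' Smallest integer case count whose [association_power()] reaches
#' `target_power` (binary search over the monotone power curve).
#'
#' @inheritParams association_power
#' @param target_power Required power (0.80 by default).
#' @param ... Passed on to [association_power()].
#' @return Integer minimum case count.
#' @examples
#' min_cases_for_power(rr = 3, maf = 0.10) # about 230
#' @export
min_cases_for_power <- function(rr, maf, target_power = 0.80, ...) {
  if (target_power <= 0 || target_power >= 1)
    stop("`target_power` must be in (0, 1)", call. = FALSE)
  pw <- function(n) association_power(rr = rr, maf = maf, n_cases = n, ...)
  if (pw(1) >= target_power) return(1L)
  hi <- 2L
  while (pw(hi) < target_power) {
    hi <- hi * 2L
    if (hi > 1e8) stop("no attainable case count below 1e8", call. = FALSE)
  }
  lo <- hi %/% 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Screening sensitivity and specificity implied by a risk variant
#'
#' Translates a hypothetical ("undetected") risk variant into test
#' performance under a dominant carrier model: carriers (frequency
#' `q = 1 - (1 - maf)^2`) develop CIAG at `rr` times the non-carrier
#' baseline risk `k`, with `k` scaled so the population risk equals
#' `prevalence`. Bayes' rule then gives the carrier fraction among cases
#' (sensitivity) and the non-carrier fraction among non-cases (specificity).
#'
#' @inheritParams association_power
#' @return A `clz_scenario_variant`: list with `rr`, `maf`, `carrier_freq`,
#'   `sensitivity`, `specificity`.
#' @examples
#' variant_sens_spec(rr = 3, maf = 0.05) # sens ~0.245, spec ~0.908
#' @export
variant_sens_spec <- function(rr, maf, prevalence = 0.0343) {
  if (rr < 1) stop("`rr` must be >= 1", call. = FALSE)
  if (maf <= 0 || maf >= 1) stop("`maf` must be in (0, 1)", call. = FALSE)
  q <- 1 - (1 - maf)^2
  k <- prevalence / (q * rr + 1 - q)
  if (rr * k > 1)
    stop("inconsistent parameters: rr * baseline risk exceeds 1", call. = FALSE)
  sens <- q * rr * k / prevalence
  spec <- 1 - q * (1 - rr * k) / (1 - prevalence)
  structure(list(rr = rr, maf = maf, carrier_freq = q,
                 sensitivity = sens, specificity = spec),
            class = "clz_scenario_variant")
}

#' @export
print.clz_scenario_variant <- function(x, ...) {
  cat(sprintf(
    "<clz_scenario_variant> RR %.2f, MAF %.3f (carriers %.4f): sens %.4f, spec %.4f\n",
    x$rr, x$maf, x$carrier_freq, x$sensitivity, x$specificity))
  invisible(x)
}

#' Scenario cost-effectiveness analysis with an augmented panel
#'
#' Adds a hypothetical risk variant (calibrated by [variant_sens_spec()]) to
#' a base panel, applies an augmented genotyping cost, and runs both the
#' deterministic comparison and a probabilistic sensitivity analysis with
#' the augmented panel performance held at its calibrated values.
#'
#' @param params A [model_parameters()] object.
#' @param rr,maf Relative risk and allele frequency of the hypothetical
#'   variant.
#' @param base_panel Panel to augment (combined HLA + SLCO panel by
#'   default).
#' @param test_cost Genotyping cost for the augmented panel (GBP; default
#'   120, the midpoint of the 110-130 band for extended panels).
#' @param n_iter,seed PSA settings.
#' @return List with the `variant`, the augmented `panel`, the
#'   `deterministic` `clz_ce`, the `psa` object and its `summary`.
#' @export
scenario_cea <- function(params, rr = 3, maf = 0.05,
                         base_panel = panel_combined(), test_cost = 120,
                         n_iter = 100000, seed = 1) {
  v <- variant_sens_spec(rr, maf, params$ciag_prevalence)
  aug <- add_variant(base_panel,
                     variant_performance(
                       sprintf("hypothetical RR=%.2g MAF=%.2g", rr, maf),
                       v$sensitivity, v$specificity))
  p <- unclass(params); p$n_cycles <- NULL; p$cost_genetic_test <- test_cost
  p <- do.call(model_parameters, p)
  det <- compare_strategies(p, aug)
  psa <- run_psa(p, aug, n_iter = n_iter, seed = seed, sample_panel = FALSE)
  list(variant = v, panel = aug, deterministic = det, psa = psa,
       summary = summary(psa))
}

#' Minimum-case and scenario-ICER grid over relative risk and allele
#' frequency
#'
#' For every (RR, MAF) combination: the minimum case count for the target
#' power, the calibrated variant performance, the augmented-panel
#' performance, and the deterministic ICER of the augmented PGx strategy.
#'
#' @param params A [model_parameters()] object.
#' @param rr_values,maf_values Grids (defaults reproduce the published
#'   3x5 layout).
#' @param base_panel Panel to augment.
#' @param test_cost Augmented genotyping cost (GBP).
#' @param ... Passed to [min_cases_for_power()].
#' @return A data frame with one row per grid cell, ordered by decreasing
#'   `rr` then decreasing `maf`.
#' @export
table2_grid <- function(params = model_parameters(),
                        rr_values = c(3.0, 2.5, 2.0),
                        maf_values = c(0.10, 0.075, 0.05, 0.025, 0.01),
                        base_panel = panel_combined(), test_cost = 120, ...) {
  cells <- expand.grid(maf = maf_values, rr = rr_values)[, c("rr", "maf")]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    rr <- cells$rr[i]; maf <- cells$maf[i]
    v <- variant_sens_spec(rr, maf, params$ciag_prevalence)
    aug <- add_variant(base_panel,
                       variant_performance("hypothetical", v$sensitivity,
                                           v$specificity))
    p <- unclass(params); p$n_cycles <- NULL; p$cost_genetic_test <- test_cost
    ce <- compare_strategies(do.call(model_parameters, p), aug)
    data.frame(rr = rr, maf = maf,
               min_cases = min_cases_for_power(rr, maf, ...),
               variant_sens = v$sensitivity, variant_spec = v$specificity,
               panel_sens = aug$sensitivity, panel_spec = aug$specificity,
               icer = ce$icer)
  })
  do.call(rbind, rows)
}
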