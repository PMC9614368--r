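#' Model parameters for the clozapine CIAG cost-effectiveness model
#'
#' Constructs and validates the full set of clinical, economic and structural
#' parameters. Defaults are the base-case input values of the model: a 3.43%
#' 10-year cumulative CIAG risk among clozapine starters, UK costs (GBP,
#' third-party payer perspective, 2019 tariffs), EQ-5D-derived utilities, a
#' 30% CIAG prevention rate for genetically flagged patients, and a 3.5%
#' annual discount rate applied to both costs and QALYs.
#'
#' @param ciag_prevalence Cumulative probability of CIAG over the horizon for
#'   a patient starting clozapine without genetic screening.
#' @param cost_ciag_treatment One-off cost (GBP) of treating a CIAG episode.
#' @param cost_clz_per_day Daily clozapine drug cost (GBP/day).
#' @param cost_substitute_per_day Daily cost of the substitute antipsychotic
#'   mix (GBP/day; usage-weighted UK first-line atypicals).
#' @param cost_genetic_test One-off cost (GBP) of the pre-emptive genotyping
#'   panel, applied to every patient in the PGx-guided arm.
#' @param cost_blood_test_per_month Monitoring blood-test cost (GBP) per
#'   cycle while on clozapine.
#' @param utility_clz Utility weight (per year) on clozapine.
#' @param utility_substitute Utility weight (per year) on the substitute.
#' @param prevention_rate Probability that foreknowledge of risk-variant
#'   carriage averts CIAG in a destined, test-positive patient.
#' @param discount_rate_annual Annual discount rate (fraction/year).
#' @param horizon_years Model horizon in years.
#' @param cycle_length_months Markov cycle length in months.
#' @param ciag_risk_window_cycles Number of initial cycles over which CIAG
#'   onset is distributed (constant hazard inside the window, zero after).
#'   The default of 36 cycles reflects that the cumulative CIAG risk is a
#'   long-term figure accrued over the first years of treatment; see the
#'   methods vignette for the rationale and a sensitivity analysis.
#' @param days_per_cycle Days per cycle used to convert per-day drug costs
#'   (365.25/12 for monthly cycles).
#'
#' @return An object of class `clz_params`: a named list of validated
#'   parameters with derived element `n_cycles`.
#' @examples
#' p <- model_parameters()
#' p$n_cycles # 120 monthly cycles over 10 years
#' @export
model_parameters <- function(ciag_prevalence = 0.0343,
                             cost_ciag_treatment = 469.48,
                             cost_clz_per_day = 1.23,
                             cost_substitute_per_day = 5.11,
                             cost_genetic_test = 110,
                             cost_blood_test_per_month = 10.6,
                             utility_clz = 0.693,
                             utility_substitute = 0.560,
                             prevention_rate = 0.30,
                             discount_rate_annual = 0.035,
                             horizon_years = 10,
                             cycle_length_months = 1,
                             ciag_risk_window_cycles = 36,
                             days_per_cycle = 365.25 / 12) {
  p <- list(
    ciag_prevalence = ciag_prevalence,
    cost_ciag_treatment = cost_ciag_treatment,
    cost_clz_per_day = cost_clz_per_day,
    cost_substitute_per_day = cost_substitute_per_day,
    cost_genetic_test = cost_genetic_test,
    cost_blood_test_per_month = cost_blood_test_per_month,
    utility_clz = utility_clz,
    utility_substitute = utility_substitute,
    prevention_rate = prevention_rate,
    discount_rate_annual = discount_rate_annual,
    horizon_years = horizon_years,
    cycle_length_months = cycle_length_months,
    ciag_risk_window_cycles = ciag_risk_window_cycles,
    days_per_cycle = days_per_cycle
  )
  validate_parameters(p)
  p$n_cycles <- as.integer(round(horizon_years * 12 / cycle_length_months))
  structure(p, class = "clz_params")
}

validate_parameters <- function(p) {
  chk_prob <- function(name) {
    x <- p[[name]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a probability in [0, 1], got %s",
                   name, format(p[[name]])), call. = FALSE)
  }
  chk_nonneg <- function(name) {
    x <- p[[name]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop(sprintf("`%s` must be a non-negative number", name), call. = FALSE)
  }
  for (nm in c("ciag_prevalence", "utility_clz", "utility_substitute",
               "prevention_rate")) chk_prob(nm)
  for (nm in c("cost_ciag_treatment", "cost_clz_per_day",
               "cost_substitute_per_day", "cost_genetic_test",
               "cost_blood_test_per_month", "discount_rate_annual",
               "days_per_cycle")) chk_nonneg(nm)
  n_cycles <- p$horizon_years * 12 / p$cycle_length_months
  if (!isTRUE(abs(n_cycles - round(n_cycles)) < 1e-9) || n_cycles < 1)
    stop("horizon_years * 12 / cycle_length_months must be a positive integer",
         call. = FALSE)
  w <- p$ciag_risk_window_cycles
  if (!is.numeric(w) || w < 1 || abs(w - round(w)) > 1e-9)
    stop("`ciag_risk_window_cycles` must be a positive integer", call. = FALSE)
  if (w > n_cycles)
    stop("`ciag_risk_window_cycles` cannot exceed the number of cycles",
         call. = FALSE)
  invisible(p)
}

#' @export
print.clz_params <- function(x, ...) {
  cat("<clz_params> CIAG cost-effectiveness model parameters\n")
  cat(sprintf("  horizon: %g years (%d cycles of %g month(s)), discount %g%%/yr\n",
              x$horizon_years, x$n_cycles, x$cycle_length_months,
              100 * x$discount_rate_annual))
  cat(sprintf("  CIAG prevalence %.4f over a %d-cycle onset window, prevention rate %.2f\n",
              x$ciag_prevalence, x$ciag_risk_window_cycles, x$prevention_rate))
  cat(sprintf("  costs: CLZ %.2f/d, substitute %.2f/d, blood test %.2f/cycle, CIAG episode %.2f, genetic test %.2f\n",
              x$cost_clz_per_day, x$cost_substitute_per_day,
              x$cost_blood_test_per_month, x$cost_ciag_treatment,
              x$cost_genetic_test))
  cat(sprintf("  utilities: clozapine %.3f, substitute %.3f\n",
              x$utility_clz, x$utility_substitute))
  invisible(x)
}

#' Probabilistic sampling distribution of a model parameter
#'
#' @param kind One of `"gamma"` (shape/rate), `"beta"` (alpha/beta) or
#'   `"fixed"`.
#' @param param_a Shape (gamma) or alpha (beta); ignored for `"fixed"`.
#' @param param_b Rate (gamma) or beta (beta); ignored for `"fixed"`.
#' @param value The constant value when `kind = "fixed"`.
#' @return A `clz_dist` object.
#' @examples
#' dist_mean(dist_spec("gamma", 37.8, 30.75)) # ~ 1.23 GBP/day
#' @export
dist_spec <- function(kind = c("gamma", "beta", "fixed"),
                      param_a = NA_real_, param_b = NA_real_,
                      value = NA_real_) {
  kind <- match.arg(kind)
  if (kind != "fixed") {
    if (!is.numeric(param_a) || !is.numeric(param_b) ||
        is.na(param_a) || is.na(param_b) || param_a <= 0 || param_b <= 0)
      stop("gamma/beta distributions need param_a > 0 and param_b > 0",
           call. = FALSE)
  } else if (is.na(value)) {
    stop("fixed distributions need `value`", call. = FALSE)
  }
  structure(list(kind = kind, param_a = param_a, param_b = param_b,
                 value = value), class = "clz_dist")
}

#' Analytic mean of a sampling distribution
#'
#' shape/rate for gamma, alpha/(alpha+beta) for beta, the constant for fixed.
#'
#' @param spec A [dist_spec()] object.
#' @return The analytic mean.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "clz_dist"))
  switch(spec$kind,
    gamma = spec$param_a / spec$param_b,
    beta  = spec$param_a / (spec$param_a + spec$param_b),
    fixed = spec$value
  )
}

# Sampling-distribution shape constants of the base-case parameter table.
# Gamma distributions are (shape, rate): shape/rate reproduces every printed
# mean (e.g. 4/0.0085 = 470.6 ~ 469.48); a shape/scale reading would not.
.table1_shapes <- list(
  cost_ciag_treatment     = c(kind = "gamma", a = 4,        b = 0.0085),
  cost_clz_per_day        = c(kind = "gamma", a = 37.8,     b = 30.75),
  cost_substitute_per_day = c(kind = "gamma", a = 104.4,    b = 20.44),
  utility_clz             = c(kind = "beta",  a = 575,      b = 255),
  utility_substitute      = c(kind = "beta",  a = 86,       b = 67),
  prevention_rate         = c(kind = "beta",  a = 24.9,     b = 58.1),
  sensitivity             = c(kind = "beta",  a = 169.13,   b = 223.87),
  specificity             = c(kind = "beta",  a = 15531.77, b = 2342.23)
)

#' Canonical parameter registry for probabilistic sensitivity analysis
#'
#' Maps every model parameter to its point estimate, its PSA sampling
#' distribution, and a flag saying whether it is varied in the PSA. Cost
#' parameters follow gamma (shape, rate) distributions; utilities, the
#' prevention rate and the panel sensitivity/specificity follow beta
#' distributions; CIAG prevalence, genetic-test cost and blood-test cost are
#' held fixed. When a supplied mean differs from the base-case value the
#' distribution is rescaled preserving its dispersion structure (gamma keeps
#' its shape, beta keeps alpha+beta), so overridden configurations remain
#' internally consistent.
#'
#' At construction every distribution's analytic mean is checked against the
#' registered mean (1% relative tolerance).
#'
#' @param params A [model_parameters()] object supplying the means.
#' @param panel A [panel_performance()] object supplying the test
#'   sensitivity/specificity means.
#' @return A `clz_registry`: named list of entries `list(mean, dist, psa)`.
#' @examples
#' reg <- default_registry()
#' registry_table(reg)
#' @export
default_registry <- function(params = model_parameters(),
                             panel = panel_combined()) {
  means <- c(
    ciag_prevalence = params$ciag_prevalence,
    cost_ciag_treatment = params$cost_ciag_treatment,
    cost_clz_per_day = params$cost_clz_per_day,
    cost_substitute_per_day = params$cost_substitute_per_day,
    cost_genetic_test = params$cost_genetic_test,
    cost_blood_test_per_month = params$cost_blood_test_per_month,
    utility_clz = params$utility_clz,
    utility_substitute = params$utility_substitute,
    prevention_rate = params$prevention_rate,
    sensitivity = panel$sensitivity,
    specificity = panel$specificity
  )
  reg <- lapply(names(means), function(nm) {
    m <- unname(means[[nm]])
    sh <- .table1_shapes[[nm]]
    if (is.null(sh)) {
      return(list(mean = m, dist = dist_spec("fixed", value = m), psa = FALSE))
    }
    a <- as.numeric(sh[["a"]]); b <- as.numeric(sh[["b"]])
    if (sh[["kind"]] == "gamma") {
      base_mean <- a / b
      if (abs(m - base_mean) / base_mean > 1e-6) b <- a / m # keep shape
      d <- dist_spec("gamma", a, b)
    } else {
      base_mean <- a / (a + b)
      if (abs(m - base_mean) / max(base_mean, 1e-12) > 1e-6) {
        size <- a + b                                       # keep alpha+beta
        a <- m * size; b <- size - a
      }
      d <- dist_spec("beta", a, b)
    }
    list(mean = m, dist = d, psa = TRUE)
  })
  names(reg) <- names(means)
  reg <- structure(reg, class = "clz_registry")
  check_registry(reg)
  reg
}

check_registry <- function(reg) {
  for (nm in names(reg)) {
    e <- reg[[nm]]
    m <- dist_mean(e$dist)
    ref <- e$mean
    if (ref > 0 && abs(m - ref) / ref > 0.01)
      stop(sprintf(
        "registry self-consistency failure: %s distribution mean %.5g vs registered mean %.5g",
        nm, m, ref), call. = FALSE)
  }
  invisible(reg)
}

#' Registry as a data frame
#'
#' @param registry A [default_registry()] object.
#' @return A data frame with columns `parameter`, `mean`, `dist_kind`,
#'   `param_a`, `param_b`, `psa`.
#' @export
registry_table <- function(registry) {
  stopifnot(inherits(registry, "clz_registry"))
  do.call(rbind, lapply(names(registry), function(nm) {
    e <- registry[[nm]]
    data.frame(parameter = nm, mean = e$mean, dist_kind = e$dist$kind,
               param_a = e$dist$param_a, param_b = e$dist$param_b,
               psa = e$psa, stringsAsFactors = FALSE)
  }))
}

#' Load model parameters from a configuration file
#'
#' The configuration is a flat YAML mapping whose keys are
#' [model_parameters()] argument names. Unspecified keys fall back to the
#' base-case defaults; unknown keys are an error (fail loud). Every override
#' is reported via `message()`.
#'
#' @param path Path to a YAML file (may be empty).
#' @param quiet Suppress override messages.
#' @return A validated `clz_params` object.
#' @seealso [write_config()]
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a flat key-value mapping", call. = FALSE)
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!quiet) {
    for (nm in names(cfg)) message(sprintf("config override: %s = %s", nm,
                                           format(cfg[[nm]])))
  }
  do.call(model_parameters, cfg)
}

#' Write model parameters to a configuration file
#'
#' @param params A `clz_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "clz_params"))
  out <- unclass(params)
  out$n_cycles <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}
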