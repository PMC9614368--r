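#' Single-variant test performance
#'
#' @param name Label for the variant (or haplotype group).
#' @param sensitivity,specificity Probabilities in \[0, 1\].
#' @return A `clz_variant` object.
#' @export
variant_performance <- function(name, sensitivity, specificity) {
  .chk_prob_vec(sensitivity, "sensitivity")
  .chk_prob_vec(specificity, "specificity")
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity), class = "clz_variant")
}

.chk_prob_vec <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x < 0 | x > 1))
    stop(sprintf("`%s` must be probabilities in [0, 1]", what), call. = FALSE)
  invisible(x)
}

#' Aggregate sensitivities of independent variants
#'
#' A panel is positive when any component is positive, so under independence
#' of variant carriage the combined sensitivity is
#' `1 - prod(1 - sensitivities)`: with the HLA haplotype group (0.360) and
#' rs149104283 (0.109), `1 - (1 - 0.360) * (1 - 0.109) = 0.430`.
#'
#' @param sens_list Numeric vector of component sensitivities.
#' @return Combined sensitivity (non-decreasing in every argument and in the
#'   number of components).
#' @examples
#' combine_sensitivity(c(0.360, 0.109)) # 0.430
#' @export
combine_sensitivity <- function(sens_list) {
  sens_list <- unlist(sens_list, use.names = FALSE)
  .chk_prob_vec(sens_list, "sens_list")
  1 - prod(1 - sens_list)
}

#' Aggregate specificities of independent variants
#'
#' A panel is negative only when every component is negative:
#' `prod(specificities)`; 0.890 x 0.976 = 0.869.
#'
#' @param spec_list Numeric vector of component specificities.
#' @return Combined specificity (non-increasing in the number of components).
#' @examples
#' combine_specificity(c(0.890, 0.976)) # 0.869
#' @export
combine_specificity <- function(spec_list) {
  spec_list <- unlist(spec_list, use.names = FALSE)
  .chk_prob_vec(spec_list, "spec_list")
  prod(spec_list)
}

#' Panel performance from component variants
#'
#' @param components A list of [variant_performance()] objects, or `NULL`
#'   when `sensitivity`/`specificity` are given directly.
#' @param sensitivity,specificity Panel-level values; computed from
#'   `components` when omitted.
#' @return A `clz_panel` with elements `sensitivity`, `specificity`,
#'   `components`.
#' @examples
#' panel_performance(list(
#'   variant_performance("HLA-DQB1(126Q)+HLA-B(158T)", 0.360, 0.890),
#'   variant_performance("rs149104283", 0.109, 0.976)
#' ))
#' @export
panel_performance <- function(components = NULL, sensitivity = NULL,
                              specificity = NULL) {
  if (!is.null(components)) {
    stopifnot(all(vapply(components, inherits, logical(1), "clz_variant")))
    if (is.null(sensitivity))
      sensitivity <- combine_sensitivity(vapply(components, `[[`, 0, "sensitivity"))
    if (is.null(specificity))
      specificity <- combine_specificity(vapply(components, `[[`, 0, "specificity"))
  }
  .chk_prob_vec(sensitivity, "sensitivity")
  .chk_prob_vec(specificity, "specificity")
  if (!is.null(components)) {
    if (sensitivity < max(vapply(components, `[[`, 0, "sensitivity")) - 1e-12)
      stop("panel sensitivity cannot be below any component sensitivity",
           call. = FALSE)
    if (specificity > min(vapply(components, `[[`, 0, "specificity")) + 1e-12)
      stop("panel specificity cannot exceed any component specificity",
           call. = FALSE)
  }
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 components = components), class = "clz_panel")
}

#' @export
print.clz_panel <- function(x, ...) {
  cat(sprintf("<clz_panel> sensitivity %.4f, specificity %.4f (%d component%s)\n",
              x$sensitivity, x$specificity,
              length(x$components),
              if (length(x$components) == 1L) "" else "s"))
  for (v in x$components)
    cat(sprintf("  - %s: sens %.3f, spec %.3f\n", v$name, v$sensitivity,
                v$specificity))
  invisible(x)
}

#' The HLA-only screening panel (sensitivity 0.360, specificity 0.890)
#' @return A `clz_panel`.
#' @export
panel_hla <- function() {
  panel_performance(list(
    variant_performance("HLA-DQB1(126Q)+HLA-B(158T)", 0.360, 0.890)
  ))
}

#' The combined HLA + SLCO1B3-SLCO1B7 panel (sensitivity 0.430,
#' specificity 0.869)
#' @return A `clz_panel`.
#' @export
panel_combined <- function() {
  panel_performance(list(
    variant_performance("HLA-DQB1(126Q)+HLA-B(158T)", 0.360, 0.890),
    variant_performance("rs149104283", 0.109, 0.976)
  ))
}

#' Add a variant to an existing panel
#'
#' @param panel A `clz_panel`.
#' @param variant A `clz_variant`.
#' @return The augmented `clz_panel`.
#' @export
add_variant <- function(panel, variant) {
  stopifnot(inherits(panel, "clz_panel"), inherits(variant, "clz_variant"))
  panel_performance(
    sensitivity = combine_sensitivity(c(panel$sensitivity, variant$sensitivity)),
    specificity = combine_specificity(c(panel$specificity, variant$specificity)),
    components = c(panel$components,
                   list(variant))[!vapply(c(panel$components, list(variant)),
                                          is.null, logical(1))]
  )
}

#' Cohort confusion fractions of a screening panel
#'
#' Splits the cohort into true/false positives/negatives given the CIAG
#' prevalence: `tp = prev * sens`, `fn = prev * (1 - sens)`,
#' `fp = (1 - prev) * (1 - spec)`, `tn = (1 - prev) * spec`.
#'
#' @param prevalence Probability of being destined for CIAG.
#' @param panel A `clz_panel`.
#' @return Named list `tp`, `fn`, `fp`, `tn` summing to 1.
#' @export
confusion_fractions <- function(prevalence, panel) {
  .chk_prob_vec(prevalence, "prevalence")
  stopifnot(inherits(panel, "clz_panel"))
  s <- panel$sensitivity; sp <- panel$specificity
  list(tp = prevalence * s,
       fn = prevalence * (1 - s),
       fp = (1 - prevalence) * (1 - sp),
       tn = (1 - prevalence) * sp)
}

#' Effective CIAG incidence under PGx-guided prevention
#'
#' Only destined patients flagged by the test benefit from prevention, so
#' the cumulative incidence falls from `prevalence` to
#' `prevalence * (1 - sensitivity * prevention_rate)`.
#'
#' @param prevalence Cumulative CIAG probability without screening.
#' @param sensitivity Panel sensitivity.
#' @param prevention_rate Probability that a flagged destined case is averted.
#' @return Effective cumulative incidence.
#' @examples
#' effective_ciag_incidence(0.0343, 0.43, 0.30) # 0.0298756
#' @export
effective_ciag_incidence <- function(prevalence, sensitivity, prevention_rate) {
  .chk_prob_vec(prevalence, "prevalence")
  .chk_prob_vec(sensitivity, "sensitivity")
  .chk_prob_vec(prevention_rate, "prevention_rate")
  prevalence * (1 - sensitivity * prevention_rate)
}

#' Number needed to genotype to prevent one CIAG case
#'
#' `100 / (prevalence_percent * sensitivity)`, rounded to the nearest
#' integer: with a 3.43% prevalence and 0.43 sensitivity, 68 screened
#' patients are needed.
#'
#' @param prevalence_percent CIAG prevalence expressed as a percentage
#'   (e.g. 3.43).
#' @param sensitivity Panel sensitivity as a probability.
#' @return Integer number of patients.
#' @examples
#' number_needed_to_genotype(3.43, 0.43) # 68
#' @export
number_needed_to_genotype <- function(prevalence_percent, sensitivity) {
  if (!is.numeric(prevalence_percent) || prevalence_percent <= 0)
    stop("`prevalence_percent` must be > 0", call. = FALSE)
  if (!is.numeric(sensitivity) || sensitivity <= 0 || sensitivity > 1)
    stop("`sensitivity` must be in (0, 1]", call. = FALSE)
  as.integer(round(100 / (prevalence_percent * sensitivity)))
}
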