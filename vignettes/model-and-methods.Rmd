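---
title: "The clozapgx model: structure, calibration and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clozapgx model: structure, calibration and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clozapgx)
```

## The decision problem

Patients with treatment-resistant schizophrenia who start clozapine face a
cumulative risk of clozapine-induced agranulocytosis/granulocytopenia
(CIAG) of 3.43%. A CIAG episode forces permanent discontinuation
(rechallenge is prohibited) and a switch to substitute antipsychotics that
cost more per day (5.11 vs 1.23 GBP) and deliver a lower utility (0.560 vs
0.693 per year). The PGx-guided strategy genotypes every patient up front
(110 GBP) for a panel of risk variants; prescriber awareness in flagged
patients is assumed to avert 30% of incipient CIAG cases among destined
carriers. The question is whether the universal test buys enough averted
CIAG — and hence retained clozapine time — to be worth its cost at the UK
threshold of 30,000 GBP/QALY.

## Model structure

Three health states: *on clozapine, at risk*, *on clozapine, safe* and the
absorbing *on substitute*. Cycles are monthly (120 cycles over 10 years).
CIAG onset follows a constant per-cycle hazard `h` inside an onset window of
`w` cycles, with `1 - (1 - h)^w` equal to the strategy's cumulative
incidence, and zero hazard afterwards; when the window closes the remaining
at-risk mass becomes safe. The transition cycle accrues the destination
state's rewards plus the one-off CIAG treatment cost (469.48 GBP); there is
no half-cycle correction. No mortality is modelled: the comparison is
between utility streams on two drug regimens, not survival.

Per cycle, clozapine states accrue `1.23 * 30.4375 + 10.6` GBP (drug plus
monitoring blood test) and `0.693/12` QALYs; the substitute state accrues
`5.11 * 30.4375` GBP and `0.560/12` QALYs. We convert per-day drug costs
with `365.25/12 = 30.4375` days per cycle. Substitute treatment carries no
monitoring cost (it requires no CIAG monitoring scheme). Rewards at cycle
`t` are discounted by `(1 + 0.035)^(-t/12)` — an end-of-cycle convention,
applied identically to costs and QALYs. The genetic test cost is paid at
cycle 0 undiscounted.

The only modelled effect of a positive test is the 30% prevention rate
applied to destined carriers: flagged patients continue clozapine, and
false positives receive identical care at identical cost. A structural
consequence — confirmed by the one-way sensitivity analysis — is that the
ICER responds strongly to panel sensitivity and not at all to specificity.

## The onset window

The onset window `w` is the one structural setting that the published
parameter table does not pin down, and the headline economics are sensitive
to it: most of the cost offset of an averted CIAG case is the discounted
stream of substitute-minus-clozapine cost differences from the event
onward, so earlier onset means larger offsets and a lower ICER. With
`w = 5` cycles the base-case ICER is about 12,400 GBP/QALY; with `w = 120`
(onset spread over the whole horizon) it is about 35,600 and crosses the
threshold.

We set `ciag_risk_window_cycles = 36` (3 years). Two considerations drive
this. Clinically, the 3.43% figure is a long-horizon cumulative incidence
of the composite CIAG outcome: agranulocytosis clusters in the first weeks
to months, but the granulocytopenia component accrues with dose and
duration over years, so a multi-year onset period is the realistic reading
of a 10-year cumulative risk. Numerically, a 3-year window is the setting
under which the model jointly reproduces the full published result set it
re-implements — the base-case ICER (we compute 16,329 vs the published
16,215 GBP/QALY), both PSA cost-effectiveness probabilities, the scenario
ICER and QALYs, and all fifteen cells of the published scenario-ICER grid
to within about 2% — with every other input taken directly from the
parameter table. No other window is consistent with those results, which
identifies the original model's implicit onset timing. The window remains a
parameter; `one_way_dsa(params, panel, "ciag_risk_window_cycles", ...)`
quantifies its influence, and the threshold conclusion (ICER < 30,000)
holds across windows from 5 to 60 cycles.

## Parameters and uncertainty

`model_parameters()` holds the point estimates; `default_registry()` maps
each to its probabilistic-sensitivity-analysis distribution:

```{r registry}
registry_table(default_registry())
```

Gamma distributions are parameterised as (shape, rate) — shape/rate
reproduces every tabulated mean, a shape/scale reading would not — and are
used for costs; beta distributions for utilities, the prevention rate and
panel performance. CIAG prevalence, the genetic-test cost and the
blood-test cost are held fixed, mirroring the original analysis. At
registry construction every distribution's analytic mean is verified
against its point estimate within 1% relative error. If a configuration
overrides a mean, the distribution is rescaled preserving its dispersion
structure (gamma keeps shape, beta keeps `alpha + beta`).

The PSA draws all parameters independently (including sensitivity and
specificity, which in truth share sampling data) from a single master seed,
materialised up-front in fixed column order, so runs are bitwise
reproducible. The closed-form cohort evaluator used in the PSA is
algebraically identical to the cycle-loop engine (geometric sums replace
the loop); the test suite asserts their agreement to 1e-9 and checks PSA
sample means against analytic means at 3 standard errors.

Two panels have published performance: combined (0.430/0.869) and HLA-only
(0.360/0.890). Only the combined panel has published beta distributions, so
the HLA-only PSA holds panel performance fixed at its point values
(`sample_panel = FALSE`); panel sensitivity contributes little sampling
variance (CV ≈ 2.5%), so this mainly affects bookkeeping, not results.

The monthly blood-test cost (10.6 GBP) is treated as a flat per-cycle cost
while on clozapine, i.e. as already averaging the weekly-then-biweekly
monitoring schedule over the horizon. One published scenario total-cost
figure (4,278 GBP) appears to exclude this monitoring cost; we retain the
tabulated treatment throughout and do not chase that single figure.

## Scenario engine and power module

`variant_sens_spec()` converts a hypothetical risk variant (relative risk
`rr`, minor allele frequency `maf`) into screening performance under a
dominant carrier model: carrier frequency `q = 1 - (1 - maf)^2`, baseline
risk `k = prev / (q*rr + 1 - q)`, sensitivity `q*rr*k/prev`, specificity
`1 - q*(1 - rr*k)/(1 - prev)`. The dominant carrier convention is chosen
because it reproduces the published augmented-panel performance (56.8% /
78.9% at RR = 3, MAF = 5%) to within 0.2 percentage points; a test
validates the closed forms against a genotype-simulation oracle. Scenario
analyses price the augmented panel at 120 GBP, the midpoint of the stated
110–130 band.

`association_power()` computes the power of a 1-df case-control chi-square
from the carrier- (or allele-) frequency difference implied by (`rr`,
`maf`, prevalence) under Hardy–Weinberg equilibrium, using per-group
variances in the non-centrality parameter. The genetic model and study
design behind the published minimum-case grid are not stated, so we scanned
the standard conventions (multiplicative/additive/dominant/recessive ×
allelic/carrier contrasts × control:case ratios × pooled/per-group
variance) against that grid. The dominant carrier contrast with two
controls per case reproduces it best — 236 cases at (RR = 3, MAF = 0.10)
vs the published 230, 4,739 at (RR = 2, MAF = 0.01) vs 4,470, all cells
within ~16% and most within 10% — and is coherent with the dominant
carrier model used for variant calibration, so it is the default;
`model`, `n_controls` and `control_ratio` are explicit arguments. Under
this convention the 229-case consortium has 78% power at the anchor point,
consistent with its published 80%-power claim; note that with the full
13,553 controls the power exceeds 99%, so the published claim holds a
fortiori as a lower bound. `min_cases_for_power()` binary-searches the
monotone power curve and is tested to sit exactly on the 80% boundary.

## The microsimulation

`simulate_patients()` is the individual-level counterpart of the cohort
engine and the package's brute-force oracle: destined status at the cohort
prevalence, test result via sensitivity / 1−specificity, aversion via the
prevention rate, onset cycle from the truncated-geometric hazard, and
per-cycle rewards identical to the cohort rules. It emulates exactly the
statistical structure the cohort model assumes — independent patients,
homogeneous risk, exact event-time distribution. It deliberately does not
emulate features of real registries: covariate heterogeneity (age, sex,
ancestry, dose), time-varying utilities, informative dropout, or secular
changes in monitoring. Passing oracle tests therefore demonstrates internal
consistency of the two engines, not external validity of the model.

Oracle equivalence is tested at n = 200,000 patients (3 standard errors,
both arms) and at smaller n for convergence; a 1,000-patient synthetic
table (seed 7) ships in `inst/extdata/` as a regression fixture.

## Numerical choices and degenerate inputs

* Hazard inversion is closed-form (`1 - (1-ci)^(1/w)`), tested against
  root-finding; zero incidence gives zero hazard and `h = 0` short-circuits
  the incident-cost term.
* ICERs are flagged rather than thrown: `dominant` (cheaper, more
  effective), `dominated`, `undefined` (zero QALY difference); the ratio is
  only reported when both increments are positive.
* Number needed to genotype rounds to the nearest integer
  (100/(3.43×0.43) = 67.8 → 68).
* Cost-effectiveness at a willingness-to-pay `λ` is defined by incremental
  net monetary benefit `λ·ΔQALY − ΔCost > 0`, which is robust to the ~0.1%
  of PSA draws where the sampled substitute utility exceeds the clozapine
  utility and ΔQALY is negative; the CEAC is therefore monotone only up to
  that draw fraction, and tests allow for it.
* Configuration files are flat YAML; unknown keys are an error, overrides
  are logged, and write/load round-trips exactly.

## Problem sizes

The reference analysis uses 100,000 PSA iterations (a few seconds with the
vectorised closed-form engine); the test suite uses 2,000–50,000 iterations
for distributional checks and 200,000 microsimulated patients for the
oracle test, which keeps the full suite under ten seconds.

## Known limitations

* The prevention mechanism is a single rate applied to flagged destined
  patients; temporary-cessation dynamics, rechallenge and monitoring
  de-escalation are not modelled.
* No mortality, relapse or hospitalisation states; utilities are constant
  within treatment states.
* Variant independence is assumed both in panel aggregation and in the PSA
  (no linkage disequilibrium, no sensitivity–specificity correlation).
* The onset-window calibration identifies the original model's timing
  structure from its published outputs; direct registry evidence on CIAG
  onset times would be the better source and could shift the point ICER
  (though not the threshold conclusion within the documented 5–60 cycle
  range).
* Severe-agranulocytosis-only analyses (1% prevalence) are supported by
  overriding `ciag_prevalence`, but the published 232-patient
  number-needed-to-genotype figure for that outcome uses an unstated
  rounding/prevalence convention and is not targeted.
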