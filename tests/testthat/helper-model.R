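# Independent reference implementation of the cohort engine, written as an
# explicit transition-matrix iteration. Used as an oracle for run_cohort().
reference_cohort <- function(params, incidence, test_cost) {
  N <- params$n_cycles
  w <- params$ciag_risk_window_cycles
  h <- 1 - (1 - incidence)^(1 / w)
  v <- (1 + params$discount_rate_annual)^(-params$cycle_length_months / 12)
  c_clz <- params$cost_clz_per_day * params$days_per_cycle +
    params$cost_blood_test_per_month
  c_sub <- params$cost_substitute_per_day * params$days_per_cycle
  u_clz <- params$utility_clz * params$cycle_length_months / 12
  u_sub <- params$utility_substitute * params$cycle_length_months / 12

  state <- c(ar = 1, safe = 0, sub = 0)
  cost <- test_cost; qaly <- 0
  for (t in seq_len(N)) {
    if (t <= w) {
      M <- rbind(c(1 - h, 0, h), c(0, 1, 0), c(0, 0, 1))
    } else {
      M <- diag(3)
    }
    new_state <- as.numeric(state %*% M)
    incident <- state[["ar"]] * if (t <= w) h else 0
    if (t == w) { # close the risk window
      new_state[2] <- new_state[2] + new_state[1]
      new_state[1] <- 0
    }
    state <- c(ar = new_state[1], safe = new_state[2], sub = new_state[3])
    on_clz <- state[["ar"]] + state[["safe"]]
    cost <- cost + v^t * (on_clz * c_clz + state[["sub"]] * c_sub +
                            incident * params$cost_ciag_treatment)
    qaly <- qaly + v^t * (on_clz * u_clz + state[["sub"]] * u_sub)
  }
  list(cost = cost, qaly = qaly)
}
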