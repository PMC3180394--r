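# Individual-level Monte Carlo microsimulation used as an independent oracle
# for the cohort engine: individuals' state paths are sampled from the same
# per-age transition matrices, and rewards are accumulated per individual, so
# the microsimulation mean estimates the cohort engine's deterministic
# expectation with a quantifiable standard error.

microsim_arm <- function(params, arm, mortality, n = 200000L, seed = 1L) {
  set.seed(seed)
  n_states <- 13L
  death <- 13L
  state <- rep(1L, n)  # everyone starts with no complications

  living <- setdiff(health_states()$name, "death")
  cost_vec <- params$base_annual_cost + params$state_marginal_costs[living]
  if (arm == "cgm") cost_vec <- cost_vec + params$cgm_annual_cost
  u0 <- params$utilities[living]

  cost <- rep(if (arm == "cgm") params$cgm_initial_cost else 0, n)
  qaly <- numeric(n)

  for (t in seq_len(params$horizon)) {
    age <- params$start_age + t - 1L
    P <- build_transition_matrix(params, arm, age, mortality)
    occupied <- setdiff(unique(state), death)
    new_state <- state
    for (s in occupied) {
      idx <- which(state == s)
      new_state[idx] <- sample.int(n_states, length(idx), replace = TRUE,
                                   prob = P[s, ])
    }
    state <- new_state
    df <- (1 + params$discount_rate)^(-t)
    alive <- state != death
    u_t <- pmax(u0 + t * params$age_disutility_per_year, 0)
    cost[alive] <- cost[alive] + cost_vec[state[alive]] * df
    qaly[alive] <- qaly[alive] + u_t[state[alive]] * df
  }
  list(
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
    n = n
  )
}
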