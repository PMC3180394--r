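# Shared fixtures, built in code. The calibrated schedule is cached for the
# test run since calibration is deterministic.

calibrated_schedule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressMessages(calibrate_mortality())
    cache
  }
})

# Flat baseline mortality (age-independent), multipliers all 1.
flat_schedule <- function(q = 0, ages = 40:105) {
  mult <- stats::setNames(rep(1, 12), setdiff(health_states()$name, "death"))
  mortality_schedule(ages, rep(q, length(ages)), mult)
}

# Parameter values with every complication transition switched off.
no_exit_values <- function() {
  tbl <- default_parameter_table()
  v <- stats::setNames(tbl$mean, tbl$name)
  v[startsWith(names(v), "p_")] <- 0
  v
}

# Parameter values with all four CGM risk reductions zeroed.
no_rrr_values <- function() {
  tbl <- default_parameter_table()
  v <- stats::setNames(tbl$mean, tbl$name)
  v[startsWith(names(v), "rrr_")] <- 0
  v
}

# Parameter table with every row downgraded to a point mass.
fixed_table <- function() {
  tbl <- default_parameter_table()
  tbl$family <- "fixed"
  tbl
}

# Hand-built PSA result from explicit (delta_cost, delta_effect) pairs.
fake_psa <- function(delta_cost, delta_effect) {
  draws <- data.frame(
    cost_smbg = 0, qaly_smbg = 0,
    cost_cgm = delta_cost, qaly_cgm = delta_effect,
    delta_cost = delta_cost, delta_effect = delta_effect
  )
  structure(list(draws = draws, n_iterations = nrow(draws), seed = 0L,
                 n_redraws = 0L),
            class = "psa_result")
}
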