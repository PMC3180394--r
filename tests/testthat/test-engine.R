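test_that("discount factors follow (1+r)^(-t)", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0.03, 33), 0.377026, tolerance = 1e-6)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_error(discount_factor(-0.01, 1))
})

test_that("transition matrix rows carry the tabulated exits and absorb the rest", {
  p <- model_parameters()
  sched <- flat_schedule(q = 0.01)
  P <- build_transition_matrix(p, "smbg", 40, sched)
  expect_equal(unname(P["no_complications",
                        c("retinopathy", "nephropathy", "neuropathy", "chd")]),
               c(0.011, 0.072, 0.035, 0.031))
  expect_equal(unname(P["no_complications", "death"]), 0.01)
  expect_equal(unname(P["no_complications", "no_complications"]),
               1 - 0.149 - 0.01)
  # terminal states: self and death only
  for (s in c("blindness", "esrd", "lea", "nephropathy_chd",
              "neuropathy_chd", "retinopathy_chd", "neuropathy_nephropathy")) {
    expect_equal(unname(P[s, s] + P[s, "death"]), 1, tolerance = 1e-15)
  }
  expect_equal(unname(P["death", ]),
               c(rep(0, 12), 1))
})

test_that("CGM arm scales additions by one minus the risk reduction", {
  p <- model_parameters()
  sched <- flat_schedule(q = 0.005)
  P <- build_transition_matrix(p, "cgm", 45, sched)
  expect_equal(unname(P["no_complications", "retinopathy"]),
               0.011 * (1 - 0.306), tolerance = 1e-9)
  expect_equal(unname(P["no_complications", "retinopathy"]), 0.0076340,
               tolerance = 1e-5)
  # the nephropathy reduction applies wherever nephropathy is added
  expect_equal(unname(P["no_complications", "nephropathy"]), 0.072 * (1 - 0.27))
  expect_equal(unname(P["neuropathy", "neuropathy_nephropathy"]),
               0.097 * (1 - 0.27))
  expect_equal(unname(P["chd", "nephropathy_chd"]), 0.022 * (1 - 0.27))
  # the CHD reduction applies to moves that add CHD
  expect_equal(unname(P["retinopathy", "retinopathy_chd"]), 0.028 * (1 - 0.05))
  # moves to blindness/ESRD/LEA add complications without a risk reduction
  expect_equal(unname(P["retinopathy", "blindness"]), 0.101)
})

test_that("zero risk reductions make the arms identical at every age", {
  p <- model_parameters(no_rrr_values())
  sched <- calibrated_schedule()
  for (age in c(40, 55, 72)) {
    expect_identical(build_transition_matrix(p, "smbg", age, sched),
                     build_transition_matrix(p, "cgm", age, sched))
  }
})

test_that("every matrix row sums to one across ages and arms", {
  p <- model_parameters()
  sched <- calibrated_schedule()
  for (arm in c("smbg", "cgm")) {
    for (age in 40:72) {
      P <- build_transition_matrix(p, arm, age, sched)
      expect_true(all(abs(rowSums(P) - 1) < 1e-12),
                  label = sprintf("row sums, %s arm age %d", arm, age))
      expect_true(all(P >= 0), label = sprintf("negativity, %s age %d", arm, age))
    }
  }
})

test_that("overloaded exit probabilities are rejected naming state and age", {
  v <- stats::setNames(default_parameter_table()$mean,
                       default_parameter_table()$name)
  v["p_neuropathy_lea"] <- 0.8
  v["p_neuropathy_nephropathy"] <- 0.25
  p <- model_parameters(v)
  sched <- flat_schedule(q = 0.01)
  expect_error(build_transition_matrix(p, "smbg", 50, sched),
               "neuropathy.*age 50")
})

test_that("state costs follow the base-plus-marginal summation rule", {
  p <- model_parameters()
  expect_equal(state_annual_cost("no_complications", p), 6705)
  expect_equal(state_annual_cost("nephropathy_chd", p), 6705 + 20161 + 35271)
  expect_equal(state_annual_cost("blindness", p), 6705 + 9912)
  expect_equal(state_annual_cost("no_complications", p, arm = "cgm", cycle = 1),
               6705 + 4189)
  # the device's annual cost does not apply in the zero cycle
  expect_equal(state_annual_cost("no_complications", p, arm = "cgm", cycle = 0),
               6705)
  expect_error(state_annual_cost("death", p), "unknown living state")
})

test_that("utilities deduct linearly with age and floor at zero", {
  p <- model_parameters()
  expect_equal(state_utility("no_complications", p, age = 40), 0.757)
  expect_equal(state_utility("no_complications", p, age = 50), 0.754)
  expect_equal(state_utility("esrd", p, age = 40), 0.521)
  steep <- model_parameters(u_age_slope = -0.1)
  expect_equal(state_utility("esrd", steep, age = 80), 0)
})

test_that("cohort trace conserves mass and death never shrinks", {
  p <- model_parameters()
  sched <- calibrated_schedule()
  for (arm in c("smbg", "cgm")) {
    res <- run_cohort(p, arm, sched)
    expect_equal(dim(res$trace), c(34L, 13L))
    expect_equal(unname(res$trace[1, ]), c(1, rep(0, 12)))
    expect_true(all(abs(rowSums(res$trace) - 1) < 1e-9))
    expect_true(all(diff(res$trace[, "death"]) >= 0))
    expect_lte(res$discounted_cost, res$undiscounted_cost)
    expect_lte(res$discounted_qalys, res$undiscounted_qalys)
  }
})

test_that("an immortal, non-progressing cohort accrues the closed-form totals", {
  v <- no_exit_values()
  v["u_no_complications"] <- 0.757
  v["u_age_slope"] <- 0
  v["discount_rate"] <- 0
  p <- model_parameters(v)
  res <- run_cohort(p, "smbg", flat_schedule(q = 0))
  expect_equal(res$discounted_qalys, 33 * 0.757, tolerance = 1e-12)
  expect_equal(res$discounted_qalys, 24.981)
  expect_equal(res$discounted_cost, 33 * 6705)
  expect_equal(res$life_years, 33)
})

test_that("the empty horizon accrues nothing except the CGM initial cost", {
  p <- model_parameters()
  sched <- flat_schedule(q = 0.01)
  smbg <- run_cohort(p, "smbg", sched, horizon = 0)
  cgm <- run_cohort(p, "cgm", sched, horizon = 0)
  expect_equal(smbg$discounted_cost, 0)
  expect_equal(smbg$discounted_qalys, 0)
  expect_equal(cgm$discounted_cost, p$cgm_initial_cost)
  expect_equal(cgm$discounted_qalys, 0)
  expect_equal(nrow(smbg$trace), 1L)
  expect_error(run_cohort(p, "smbg", sched, horizon = -1),
               "invalid configuration")
})

test_that("zero discounting equates discounted and undiscounted totals", {
  p <- model_parameters(discount_rate = 0)
  sched <- calibrated_schedule()
  res <- run_cohort(p, "cgm", sched)
  expect_identical(res$discounted_cost, res$undiscounted_cost)
  expect_identical(res$discounted_qalys, res$undiscounted_qalys)
})

test_that("with zero risk reductions the arms differ only by device costs", {
  p <- model_parameters(no_rrr_values())
  sched <- calibrated_schedule()
  smbg <- run_cohort(p, "smbg", sched)
  cgm <- run_cohort(p, "cgm", sched)
  expect_equal(cgm$trace, smbg$trace, tolerance = 1e-15)
  ce <- compare_arms(smbg, cgm)
  expect_equal(ce$delta_effect, 0, tolerance = 1e-12)
  # the cost difference is exactly the discounted device stream weighted by
  # survival
  alive <- 1 - smbg$trace[-1, "death"]
  t <- seq_along(alive)
  device <- p$cgm_initial_cost +
    sum(p$cgm_annual_cost * alive * (1 + p$discount_rate)^(-t))
  expect_equal(ce$delta_cost, device, tolerance = 1e-9)
})

test_that("raising any single risk reduction never lowers CGM-arm QALYs", {
  sched <- calibrated_schedule()
  base_v <- stats::setNames(default_parameter_table()$mean,
                            default_parameter_table()$name)
  base_q <- run_cohort(model_parameters(base_v), "cgm", sched)$discounted_qalys
  for (nm in c("rrr_retinopathy", "rrr_nephropathy", "rrr_neuropathy",
               "rrr_chd")) {
    v <- base_v
    v[nm] <- min(v[nm] + 0.2, 1)
    q <- run_cohort(model_parameters(v), "cgm", sched)$discounted_qalys
    expect_gte(q, base_q)
  }
})

test_that("incremental comparison reproduces the printed ratio and flags dominance", {
  ce <- incremental_result(23552, 0.523)
  expect_equal(ce$icer, 23552 / 0.523)
  expect_equal(round(ce$icer), 45033)
  expect_equal(ce$dominance, "none")

  expect_equal(incremental_result(-1, 0.1)$dominance, "intervention_dominant")
  expect_equal(incremental_result(10, -0.1)$dominance, "intervention_dominated")
  same <- incremental_result(0, 0)
  expect_equal(same$dominance, "none")
  expect_true(is.na(same$icer))
  # equal effectiveness, higher cost: dominance by cost, no defined ICER
  bycost <- incremental_result(100, 0)
  expect_equal(bycost$dominance, "intervention_dominated")
  expect_true(is.na(bycost$icer))
})

test_that("net monetary benefit is wtp times effect minus cost", {
  ce <- incremental_result(23552, 0.523)
  expect_equal(net_monetary_benefit(50000, ce), 2598)
  expect_equal(net_monetary_benefit(100000, ce), 28748)
  expect_equal(net_monetary_benefit(0, ce), -23552)
  expect_error(net_monetary_benefit(-1, ce))
})

test_that("a small microsimulation agrees with the cohort expectation", {
  p <- model_parameters()
  sched <- calibrated_schedule()
  cohort <- run_cohort(p, "smbg", sched)
  ms <- microsim_arm(p, "smbg", sched, n = 20000L, seed = 11L)
  expect_lt(abs(ms$mean_cost - cohort$discounted_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$mean_qaly - cohort$discounted_qalys), 3 * ms$se_qaly)
})
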