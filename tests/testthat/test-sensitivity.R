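test_that("a zero-variance PSA collapses to the deterministic base case", {
  sched <- calibrated_schedule()
  bc <- run_base_case(model_parameters(), sched)
  psa <- run_psa(fixed_table(), sched, n = 5, seed = 3)
  expect_equal(psa$n_iterations, 5L)
  for (i in 1:5) {
    expect_equal(psa$draws$cost_smbg[i], bc$smbg$discounted_cost)
    expect_equal(psa$draws$qaly_cgm[i], bc$cgm$discounted_qalys)
    expect_equal(psa$draws$delta_cost[i], bc$ce$delta_cost)
    expect_equal(psa$draws$delta_effect[i], bc$ce$delta_effect)
  }
})

test_that("the PSA is bit-reproducible from its seed", {
  sched <- calibrated_schedule()
  p1 <- run_psa(n = 25, seed = 123, mortality = sched)
  p2 <- run_psa(n = 25, seed = 123, mortality = sched)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(n = 25, seed = 124, mortality = sched)
  expect_false(identical(p1$draws, p3$draws))
  expect_error(run_psa(n = 5, mortality = sched), "seed")
})

test_that("PSA draw records are internally consistent", {
  sched <- calibrated_schedule()
  psa <- run_psa(n = 25, seed = 5, mortality = sched)
  expect_equal(psa$draws$delta_cost,
               psa$draws$cost_cgm - psa$draws$cost_smbg)
  expect_equal(psa$draws$delta_effect,
               psa$draws$qaly_cgm - psa$draws$qaly_smbg)
})

test_that("quadrant fractions follow the stated axis conventions", {
  # one point per quadrant
  psa <- fake_psa(delta_cost = c(10000, -10000, 10000, -10000),
                  delta_effect = c(1, 1, -1, -1))
  fr <- quadrant_fractions(psa, wtp = 50000)
  expect_equal(unname(fr["fraction_se"]), 0.25)
  expect_equal(unname(fr["fraction_ne_below_wtp"]), 0.25)
  expect_equal(unname(fr["fraction_cost_effective"]), 0.5)
  part <- quadrant_partition(psa)
  expect_equal(sum(part), 1)
  expect_equal(unname(part), rep(0.25, 4))

  # axis points: dC = 0 counts as north; dE = 0 joins neither SE nor NE
  onaxis <- fake_psa(delta_cost = c(0, 5000), delta_effect = c(1, 0))
  fr2 <- quadrant_fractions(onaxis, wtp = 50000)
  expect_equal(unname(fr2["fraction_se"]), 0)
  expect_equal(unname(fr2["fraction_ne_below_wtp"]), 0.5)
  expect_equal(sum(quadrant_partition(onaxis)), 1)

  # a degenerate all-dominant cloud
  dom <- fake_psa(delta_cost = rep(-1, 4), delta_effect = rep(0.1, 4))
  expect_equal(unname(quadrant_fractions(dom, 0)["fraction_se"]), 1)
})

test_that("the acceptability curve steps where net benefit crosses zero", {
  single <- fake_psa(delta_cost = 25000, delta_effect = 0.5)
  curve <- ceac(single, c(0, 49999, 50000, 50001, 100000))
  expect_equal(curve$probability, c(0, 0, 0, 1, 1))
  # with all dE > 0 the curve is non-decreasing, reaching 1; at wtp 0 it
  # equals the share of cost-saving draws
  psa <- fake_psa(delta_cost = c(-5000, 10000, 30000),
                  delta_effect = c(0.2, 0.4, 0.6))
  curve2 <- ceac(psa, seq(0, 2e5, by = 1e4))
  expect_true(all(diff(curve2$probability) >= 0))
  expect_equal(curve2$probability[1], 1 / 3)
  expect_equal(curve2$probability[nrow(curve2)], 1)
})

test_that("ceac split halves agree within Monte Carlo error", {
  sched <- calibrated_schedule()
  psa <- run_psa(n = 1000, seed = 17, mortality = sched)
  half <- seq_len(500)
  p1 <- mean(1e5 * psa$draws$delta_effect[half] - psa$draws$delta_cost[half] > 0)
  p2 <- mean(1e5 * psa$draws$delta_effect[-half] - psa$draws$delta_cost[-half] > 0)
  p <- (p1 + p2) / 2
  se_diff <- sqrt(2 * p * (1 - p) / 500)
  expect_lt(abs(p1 - p2), 3 * se_diff + 1e-12)
})

test_that("tornado ranks by spread and nulls behave as expected", {
  sched <- calibrated_schedule()
  torn <- tornado(mortality = sched, wtp = 1e5, pct = 0.15)
  expect_true(all(diff(torn$spread) <= 0))
  # ranged parameters only: fixed settings are never perturbed
  expect_false(any(c("start_age", "horizon", "discount_rate", "u_age_slope")
                   %in% torn$parameter))
  # the repeat-amputation probability is a cost- and utility-neutral
  # self-loop, so the model never reads it: spread exactly 0
  expect_equal(torn$spread[torn$parameter == "p_subsequent_lea"], 0)
  # a null perturbation gives all-zero spreads
  torn0 <- tornado(mortality = sched, pct = 0)
  expect_true(all(torn0$spread == 0))
})

test_that("probes multiply one parameter and reduce to the base case at 1", {
  sched <- calibrated_schedule()
  base <- run_base_case(model_parameters(), sched)$ce
  same <- probe_icer("c_chd", 1, mortality = sched)
  expect_equal(same$icer, base$icer)
  expect_equal(same$delta_cost, base$delta_cost)
  up <- probe_icer("c_chd", 1.5, mortality = sched)
  expect_false(isTRUE(all.equal(up$icer, base$icer)))
  expect_error(probe_icer("c_chd", 0, mortality = sched))
  expect_error(probe_icer("no_such_param", 1.5, mortality = sched),
               "unknown parameter")
  # beta-bounded quantities are clipped with a notice
  expect_message(clipped <- probe_icer("u_no_complications", 1.5,
                                       mortality = sched),
                 "clipped")
})
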