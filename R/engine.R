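# Deterministic two-arm Markov cohort engine: per-age transition matrices,
# cohort trace, discounted cost/QALY accrual and incremental comparison.

.ARMS <- c("smbg", "cgm")
.N_STATES <- length(.STATE_NAMES)
.DEATH_IDX <- match(.DEATH, .STATE_NAMES)

#' Discount factor
#'
#' Present-value weight `(1 + rate)^(-t)` applied to a reward accrued at the
#' end of cycle `t`.
#'
#' @param rate Annual discount rate (>= 0); the model default is 0.03.
#' @param t Cycle index (non-negative integer, vectorised).
#' @return Dimensionless factor(s) in (0, 1].
#' @examples
#' discount_factor(0.03, 0:3)
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

# Exit-probability matrix (13 x 13, zero diagonal, zero death column) for one
# arm. Age-independent; death and the self-transition are filled per cycle.
.exit_matrix <- function(params, arm) {
  arm <- match.arg(arm, .ARMS)
  E <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(.STATE_NAMES, .STATE_NAMES))
  tr <- .TRANSITIONS
  p <- params$transition_probs[tr$param]
  if (arm == "cgm") {
    has_rrr <- !is.na(tr$adds)
    p[has_rrr] <- p[has_rrr] * (1 - params$risk_reductions[tr$adds[has_rrr]])
  }
  for (i in seq_len(nrow(tr))) {
    E[tr$from[i], tr$to[i]] <- E[tr$from[i], tr$to[i]] + p[i]
  }
  E
}

.death_probs <- function(params, mortality, age) {
  q <- .baseline_q_at(mortality, age)
  pmin(q * mortality$multipliers[.LIVING_STATES], 1)
}

#' Build the one-cycle transition matrix for an arm at a given age
#'
#' Assembles the row-stochastic 13x13 annual transition matrix. The death
#' probability of each living state is the baseline all-cause probability at
#' `age` times the state's hazard multiplier (capped at 1); complication
#' transitions enter with their tabulated annual probabilities -- multiplied,
#' in the CGM arm, by `(1 - risk reduction)` for the complication the move
#' adds -- and the self-transition absorbs the remainder. Death is absorbing.
#'
#' @param params A `cea_parameters` object.
#' @param arm `"smbg"` or `"cgm"`.
#' @param age Age in years during the cycle; must be covered by the schedule.
#' @param mortality A `mortality_schedule`.
#' @return A 13x13 row-stochastic matrix with dimnames of state names.
#' @examples
#' P <- build_transition_matrix(model_parameters(), "smbg", 40,
#'                              generate_mortality_schedule(a = 5e-5))
#' rowSums(P)
#' @export
build_transition_matrix <- function(params, arm, age, mortality) {
  E <- .exit_matrix(params, arm)
  .assemble_matrix(E, rowSums(E), .death_probs(params, mortality, age), age)
}

.assemble_matrix <- function(E, exit_sums, death, age) {
  self <- 1 - exit_sums[.LIVING_STATES] - death
  neg <- self < 0
  if (any(neg)) {
    if (any(self < -1e-12)) {
      worst <- names(self)[which.min(self)]
      stop("invalid parameter set: exits plus death exceed 1 in state '",
           worst, "' at age ", age, " (residual ", signif(min(self), 4), ")")
    }
    self[neg] <- 0
  }
  P <- E
  P[.LIVING_STATES, .DEATH_IDX] <- death
  diag(P)[.LIVING_STATES] <- self
  P[.DEATH_IDX, ] <- 0
  P[.DEATH_IDX, .DEATH_IDX] <- 1
  P
}

#' Annual cost of occupying a state
#'
#' Base annual diabetes cost plus the state's marginal cost; composite states
#' sum their components' marginals (blindness, LEA and ESRD carry single
#' marginals). In the CGM arm the annual device cost is added to every living
#' state from cycle 1 onwards; the initial device cost is handled separately
#' at cycle 0 by [run_cohort()].
#'
#' @param state Living state name(s).
#' @param params A `cea_parameters` object.
#' @param arm `"smbg"` or `"cgm"`.
#' @param cycle Cycle index (device cost applies when `cycle >= 1`).
#' @return Annual cost(s) in 2007 US$.
#' @examples
#' state_annual_cost("nephropathy_chd", model_parameters())
#' @export
state_annual_cost <- function(state, params, arm = "smbg", cycle = 1L) {
  arm <- match.arg(arm, .ARMS)
  bad <- setdiff(state, .LIVING_STATES)
  if (length(bad) > 0L) {
    stop("unknown living state(s): ", paste(bad, collapse = ", "))
  }
  cost <- params$base_annual_cost + params$state_marginal_costs[state]
  if (arm == "cgm" && cycle >= 1L) cost <- cost + params$cgm_annual_cost
  unname(cost)
}

#' Age-adjusted utility of occupying a state
#'
#' Tabulated EQ-5D utility at the start age plus a linear age deduction
#' (`age_disutility_per_year`, negative), floored at 0.
#'
#' @param state Living state name(s).
#' @param params A `cea_parameters` object.
#' @param age Attained age in years (>= start age).
#' @return Utility weight(s).
#' @examples
#' state_utility("no_complications", model_parameters(), age = 50)
#' @export
state_utility <- function(state, params, age) {
  bad <- setdiff(state, .LIVING_STATES)
  if (length(bad) > 0L) {
    stop("unknown living state(s): ", paste(bad, collapse = ", "))
  }
  u <- params$utilities[state] +
    (age - params$start_age) * params$age_disutility_per_year
  pmax(unname(u), 0)
}

#' Run the Markov cohort for one arm
#'
#' The cohort starts entirely in the no-complication state at cycle 0 and is
#' pushed through one transition matrix per one-year cycle (ages advance with
#' cycles). Rewards accrue at the end of each cycle `t = 1..horizon`: the
#' end-of-cycle occupancy of each living state earns that state's annual cost
#' and its age-adjusted utility, both discounted by `(1 + r)^(-t)`. No
#' half-cycle correction is applied. The CGM arm additionally pays the
#' initial device cost at cycle 0 (undiscounted) and the annual device cost
#' in every living state from cycle 1 on.
#'
#' @param params A `cea_parameters` object.
#' @param arm `"smbg"` or `"cgm"`.
#' @param mortality A `mortality_schedule` covering ages
#'   `start_age .. start_age + horizon - 1`.
#' @param horizon Number of one-year cycles; defaults to `params$horizon`.
#' @return An object of class `arm_result`: `arm`, `discounted_cost`,
#'   `discounted_qalys`, `undiscounted_cost`, `undiscounted_qalys`,
#'   `life_years`, and `trace` (the `(horizon+1) x 13` occupancy matrix).
#' @examples
#' sched <- generate_mortality_schedule(a = 5e-5)
#' res <- run_cohort(model_parameters(), "smbg", sched)
#' res$discounted_qalys
#' @export
run_cohort <- function(params, arm, mortality, horizon = params$horizon) {
  arm <- match.arg(arm, .ARMS)
  horizon <- as.integer(horizon)
  if (horizon < 0L) stop("invalid configuration: horizon must be >= 0")

  E <- .exit_matrix(params, arm)
  exit_sums <- rowSums(E)
  mult <- mortality$multipliers[.LIVING_STATES]

  trace <- matrix(0, horizon + 1L, .N_STATES,
                  dimnames = list(0:horizon, .STATE_NAMES))
  occ <- stats::setNames(numeric(.N_STATES), .STATE_NAMES)
  occ["no_complications"] <- 1
  trace[1L, ] <- occ

  cost_vec <- state_annual_cost(.LIVING_STATES, params, arm = arm, cycle = 1L)
  u0 <- params$utilities[.LIVING_STATES]
  r <- params$discount_rate
  living_idx <- seq_len(.N_STATES - 1L)

  disc_cost <- undisc_cost <- 0
  disc_qaly <- undisc_qaly <- 0
  life_years <- 0
  if (arm == "cgm") {
    disc_cost <- undisc_cost <- params$cgm_initial_cost
  }

  for (t in seq_len(horizon)) {
    age_in_cycle <- params$start_age + t - 1L
    q <- pmin(.baseline_q_at(mortality, age_in_cycle) * mult, 1)
    P <- .assemble_matrix(E, exit_sums, q, age_in_cycle)
    occ <- drop(occ %*% P)
    trace[t + 1L, ] <- occ

    living <- occ[living_idx]
    cost_t <- sum(living * cost_vec)
    u_t <- pmax(u0 + t * params$age_disutility_per_year, 0)
    qaly_t <- sum(living * u_t)
    df <- (1 + r)^(-t)

    undisc_cost <- undisc_cost + cost_t
    disc_cost <- disc_cost + cost_t * df
    undisc_qaly <- undisc_qaly + qaly_t
    disc_qaly <- disc_qaly + qaly_t * df
    life_years <- life_years + sum(living)
  }

  structure(
    list(arm = arm,
         discounted_cost = disc_cost, discounted_qalys = disc_qaly,
         undiscounted_cost = undisc_cost, undiscounted_qalys = undisc_qaly,
         life_years = life_years, trace = trace),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm: discounted cost $%s, %.3f QALYs (%.2f life-years)\n",
              toupper(x$arm), format(round(x$discounted_cost), big.mark = ","),
              x$discounted_qalys, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness from raw increments
#'
#' @param delta_cost Incremental cost (intervention minus comparator), US$.
#' @param delta_effect Incremental effectiveness, QALYs.
#' @return An object of class `ce_result`: `delta_cost`, `delta_effect`,
#'   `icer` (US$/QALY, `NA` when undefined), `dominance` (`"none"`,
#'   `"intervention_dominant"`, `"intervention_dominated"`).
#' @export
incremental_result <- function(delta_cost, delta_effect) {
  dominance <- "none"
  icer <- NA_real_
  if (delta_effect == 0) {
    if (delta_cost < 0) dominance <- "intervention_dominant"
    if (delta_cost > 0) dominance <- "intervention_dominated"
  } else if (delta_cost <= 0 && delta_effect > 0) {
    dominance <- "intervention_dominant"
    icer <- delta_cost / delta_effect
  } else if (delta_cost >= 0 && delta_effect < 0) {
    dominance <- "intervention_dominated"
    icer <- delta_cost / delta_effect
  } else {
    icer <- delta_cost / delta_effect
  }
  structure(
    list(delta_cost = delta_cost, delta_effect = delta_effect,
         icer = icer, dominance = dominance),
    class = "ce_result"
  )
}

#' Compare the two arms
#'
#' Incremental discounted cost and QALYs of CGM over SMBG, with the ICER or a
#' dominance flag.
#'
#' @param smbg,cgm `arm_result` objects from [run_cohort()] computed under the
#'   same parameters and mortality schedule.
#' @return A `ce_result`; see [incremental_result()].
#' @export
compare_arms <- function(smbg, cgm) {
  incremental_result(cgm$discounted_cost - smbg$discounted_cost,
                     cgm$discounted_qalys - smbg$discounted_qalys)
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental cost $%s, incremental effectiveness %.3f QALYs\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_effect))
  if (x$dominance != "none") {
    cat("  ", gsub("_", " ", x$dominance), "\n", sep = "")
  }
  if (is.finite(x$icer)) {
    cat(sprintf("  ICER $%s/QALY\n", format(round(x$icer), big.mark = ",")))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * delta_effect - delta_cost`: positive when the intervention is
#' cost-effective at the given willingness-to-pay.
#'
#' @param wtp Willingness-to-pay threshold, US$/QALY (>= 0).
#' @param ce A `ce_result`, or anything with `delta_cost`/`delta_effect`.
#' @return Net monetary benefit in US$.
#' @examples
#' net_monetary_benefit(50000, incremental_result(23552, 0.523))
#' @export
net_monetary_benefit <- function(wtp, ce) {
  stopifnot(wtp >= 0)
  wtp * ce$delta_effect - ce$delta_cost
}

#' Run the base case: both arms plus the incremental comparison
#'
#' @param params A `cea_parameters` object (defaults to the point estimates).
#' @param mortality A `mortality_schedule`; defaults to the synthetic
#'   schedule calibrated to life expectancy 73.
#' @return An object of class `base_case`: `smbg`, `cgm` (`arm_result`s) and
#'   `ce` (`ce_result`).
#' @examples
#' \donttest{
#' bc <- run_base_case()
#' bc$ce$icer
#' }
#' @export
run_base_case <- function(params = model_parameters(),
                          mortality = calibrate_mortality(params = params)) {
  smbg <- run_cohort(params, "smbg", mortality)
  cgm <- run_cohort(params, "cgm", mortality)
  structure(list(smbg = smbg, cgm = cgm, ce = compare_arms(smbg, cgm)),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  fmt <- function(v) format(round(v), big.mark = ",")
  cat("Strategy  Expected cost (2007 US$)  Expected effectiveness (QALYs)\n")
  cat(sprintf("SMBG      %24s  %30.3f\n", fmt(x$smbg$discounted_cost),
              x$smbg$discounted_qalys))
  cat(sprintf("CGM+SMBG  %24s  %30.3f\n", fmt(x$cgm$discounted_cost),
              x$cgm$discounted_qalys))
  print(x$ce)
  invisible(x)
}
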