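# Probabilistic (Monte Carlo) and univariate (tornado) sensitivity analyses
# over the cohort engine.

#' Probabilistic sensitivity analysis
#'
#' Draws `n` full parameter sets from the fitted beta/gamma distributions and
#' runs both arms of the cohort engine under each draw (common random
#' parameters across arms). Mortality is held fixed: the schedule carries no
#' published uncertainty ranges. Draws that produce an invalid transition
#' matrix (exits plus death exceeding 1 in some state) are redrawn; the run
#' aborts if more than `max_redraw_frac` of iterations need a redraw.
#'
#' @param table Parameter table with uncertainty ranges
#'   (default [default_parameter_table()]).
#' @param mortality A `mortality_schedule`.
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed; mandatory, so every PSA is reproducible.
#' @param max_redraw_frac Abort threshold on the redraw fraction.
#' @return An object of class `psa_result`: `draws` (data frame with columns
#'   `cost_smbg`, `qaly_smbg`, `cost_cgm`, `qaly_cgm`, `delta_cost`,
#'   `delta_effect`), `n_iterations`, `seed`, `n_redraws`.
#' @examples
#' \donttest{
#' sched <- calibrate_mortality()
#' psa <- run_psa(n = 100, seed = 1, mortality = sched)
#' quadrant_fractions(psa, wtp = 50000)
#' }
#' @export
run_psa <- function(table = default_parameter_table(), mortality,
                    n = 10000L, seed, max_redraw_frac = 0.01) {
  if (missing(seed) || is.null(seed)) {
    stop("run_psa() requires an explicit seed")
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  set.seed(seed)
  fitted <- fit_parameter_distributions(table)
  draws_mat <- sample_parameter_matrix(fitted, n = n)

  out <- matrix(NA_real_, n, 6L, dimnames = list(NULL, c(
    "cost_smbg", "qaly_smbg", "cost_cgm", "qaly_cgm",
    "delta_cost", "delta_effect")))
  n_redraws <- 0L
  max_redraws <- max(1, ceiling(max_redraw_frac * n))

  for (i in seq_len(n)) {
    repeat {
      res <- tryCatch({
        p <- model_parameters(draws_mat[i, ])
        smbg <- run_cohort(p, "smbg", mortality)
        cgm <- run_cohort(p, "cgm", mortality)
        c(smbg$discounted_cost, smbg$discounted_qalys,
          cgm$discounted_cost, cgm$discounted_qalys)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) {
        stop("PSA aborted: more than ", round(100 * max_redraw_frac, 2),
             "% of iterations produced invalid parameter sets; last error: ",
             conditionMessage(res))
      }
      draws_mat[i, ] <- sample_parameter_matrix(fitted, n = 1L)
    }
    out[i, ] <- c(res, res[3] - res[1], res[4] - res[2])
  }
  if (n_redraws > 0L) {
    message(n_redraws, " PSA iteration(s) redrawn due to invalid parameter sets")
  }
  structure(
    list(draws = as.data.frame(out), n_iterations = n, seed = seed,
         n_redraws = n_redraws),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s)\n", x$n_iterations,
              format(x$seed)))
  cat(sprintf("  mean dC $%s, mean dE %.3f QALYs\n",
              format(round(mean(x$draws$delta_cost)), big.mark = ","),
              mean(x$draws$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness-plane quadrant fractions
#'
#' Shares of PSA draws in regions of the incremental cost-effectiveness
#' plane. Axis convention: draws with `delta_cost = 0` count as
#' north (non-negative cost); draws with `delta_effect = 0` belong to neither
#' SE nor NE-below-threshold (both require `delta_effect > 0`).
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @return Named vector: `fraction_se` (cheaper and more effective --
#'   intervention dominant), `fraction_ne_below_wtp` (costlier, more
#'   effective, ICER under the threshold), `fraction_cost_effective`
#'   (positive net monetary benefit at `wtp`).
#' @export
quadrant_fractions <- function(psa, wtp) {
  d <- psa$draws
  stopifnot(nrow(d) > 0L)
  se <- d$delta_cost < 0 & d$delta_effect > 0
  ne_below <- d$delta_cost >= 0 & d$delta_effect > 0 &
    d$delta_cost / d$delta_effect < wtp
  nmb <- wtp * d$delta_effect - d$delta_cost
  c(fraction_se = mean(se),
    fraction_ne_below_wtp = mean(ne_below),
    fraction_cost_effective = mean(nmb > 0))
}

#' Full quadrant partition of the cost-effectiveness plane
#'
#' @param psa A `psa_result`.
#' @return Named vector over `ne`, `se`, `nw`, `sw` summing to 1; draws on
#'   the cost axis (`delta_cost = 0`) count as north, draws on the effect
#'   axis (`delta_effect = 0`) as west.
#' @export
quadrant_partition <- function(psa) {
  d <- psa$draws
  north <- d$delta_cost >= 0
  east <- d$delta_effect > 0
  c(ne = mean(north & east), se = mean(!north & east),
    nw = mean(north & !east), sw = mean(!north & !east))
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective (positive net monetary
#' benefit) at each willingness-to-pay value.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Ascending vector of willingness-to-pay values, US$/QALY.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(!is.unsorted(wtp_grid))
  d <- psa$draws
  prob <- vapply(wtp_grid,
                 function(w) mean(w * d$delta_effect - d$delta_cost > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

# Perturbed copy of the base values for one parameter; beta-family quantities
# are clipped to [0, 1].
.perturb_value <- function(table, values, name, new_value) {
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  if (table$family[i] == "beta" || table$group[i] %in%
      c("probability", "utility", "risk_reduction")) {
    clipped <- min(max(new_value, 0), 1)
    if (clipped != new_value) {
      message("parameter '", name, "' clipped to [0, 1] (", signif(new_value, 4),
              " -> ", signif(clipped, 4), ")")
      if (abs(clipped - new_value) > abs(new_value - values[[name]])) {
        warning("clipping of '", name,
                "' exceeds the intended perturbation")
      }
    }
    new_value <- clipped
  }
  values[name] <- new_value
  values
}

#' Univariate tornado analysis on net monetary benefit
#'
#' Perturbs each uncertain parameter one at a time to `mean * (1 - pct)` and
#' `mean * (1 + pct)` (all others at their means), reruns both arms, and
#' records the net monetary benefit at `wtp` each way. Fixed settings (start
#' age, horizon, discount rate, age disutility) are not varied. Perturbed
#' beta-family quantities are clipped to `[0, 1]`.
#'
#' @param table Parameter table.
#' @param mortality A `mortality_schedule`.
#' @param wtp Willingness-to-pay for the net-monetary-benefit outcome,
#'   US$/QALY (default 100,000).
#' @param pct Perturbation fraction (default 0.15).
#' @return An object of class `tornado_result`: a data frame sorted by
#'   descending `spread` with columns `parameter`, `label`, `value_low`,
#'   `value_high`, `nmb_low`, `nmb_high`, `spread`, plus attributes `wtp`,
#'   `pct` and `base_nmb`.
#' @examples
#' \donttest{
#' sched <- calibrate_mortality()
#' head(tornado(mortality = sched))
#' }
#' @export
tornado <- function(table = default_parameter_table(), mortality,
                    wtp = 1e5, pct = 0.15) {
  stopifnot(pct >= 0, pct < 1)
  base_values <- stats::setNames(table$mean, table$name)
  nmb_for <- function(values) {
    bc <- run_base_case(model_parameters(values), mortality)
    net_monetary_benefit(wtp, bc$ce)
  }
  base_nmb <- nmb_for(base_values)
  ranged <- which(table$family != "fixed")
  rows <- lapply(ranged, function(i) {
    name <- table$name[i]
    v_lo <- .perturb_value(table, base_values, name, table$mean[i] * (1 - pct))
    v_hi <- .perturb_value(table, base_values, name, table$mean[i] * (1 + pct))
    nmb_lo <- if (pct == 0) base_nmb else nmb_for(v_lo)
    nmb_hi <- if (pct == 0) base_nmb else nmb_for(v_hi)
    data.frame(parameter = name, label = table$label[i],
               value_low = v_lo[[name]], value_high = v_hi[[name]],
               nmb_low = nmb_lo, nmb_high = nmb_hi,
               spread = abs(nmb_hi - nmb_lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado_result", "data.frame"),
            wtp = wtp, pct = pct, base_nmb = base_nmb)
}

#' One-way ICER probe
#'
#' Multiplies a single parameter by `factor` (all others at their means),
#' reruns the base case and returns the incremental comparison. Used for the
#' +/-50\% probes of the top tornado parameters.
#'
#' @param param_name Parameter to perturb.
#' @param factor Positive multiplier.
#' @param table Parameter table.
#' @param mortality A `mortality_schedule`.
#' @return A `ce_result`.
#' @examples
#' \donttest{
#' sched <- calibrate_mortality()
#' probe_icer("c_chd", 1.5, mortality = sched)$icer
#' }
#' @export
probe_icer <- function(param_name, factor, table = default_parameter_table(),
                       mortality) {
  stopifnot(factor > 0)
  base_values <- stats::setNames(table$mean, table$name)
  i <- match(param_name, table$name)
  if (is.na(i)) stop("unknown parameter: ", param_name)
  values <- .perturb_value(table, base_values, param_name,
                           table$mean[i] * factor)
  run_base_case(model_parameters(values), mortality)$ce
}
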