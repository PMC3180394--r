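# Point estimates and credible ranges for every model input, and the
# construction of a complete parameter set from a named value vector.

.PARAM_TABLE <- local({
  row <- function(name, group, label, mean, lo = NA_real_, hi = NA_real_,
                  family = c("beta", "gamma", "fixed")) {
    data.frame(name = name, group = group, label = label, mean = mean,
               lo = lo, hi = hi, family = match.arg(family),
               stringsAsFactors = FALSE)
  }
  rbind(
    # Annual transition probabilities
    row("p_retinopathy_blindness", "probability", "Retinopathy to blindness", 0.101, 0.057, 0.156, "beta"),
    row("p_nc_chd", "probability", "Diabetes with no complications to CHD", 0.031, 0.018, 0.048, "beta"),
    row("p_subsequent_lea", "probability", "Subsequent LEA", 0.110, 0.062, 0.169, "beta"),
    row("p_nc_nephropathy", "probability", "Diabetes with no complications to nephropathy", 0.072, 0.041, 0.112, "beta"),
    row("p_nephropathy_chd", "probability", "Nephropathy to CHD", 0.022, 0.013, 0.034, "beta"),
    row("p_nephropathy_esrd", "probability", "Nephropathy to ESRD", 0.072, 0.041, 0.109, "beta"),
    row("p_nc_neuropathy", "probability", "Diabetes with no complications to neuropathy", 0.035, 0.020, 0.055, "beta"),
    row("p_neuropathy_chd", "probability", "Neuropathy to CHD", 0.029, 0.016, 0.044, "beta"),
    row("p_neuropathy_lea", "probability", "Neuropathy to LEA", 0.131, 0.074, 0.200, "beta"),
    row("p_neuropathy_nephropathy", "probability", "Neuropathy to nephropathy", 0.097, 0.055, 0.149, "beta"),
    row("p_nc_retinopathy", "probability", "Diabetes with no complications to retinopathy", 0.011, 0.006, 0.017, "beta"),
    row("p_retinopathy_chd", "probability", "Retinopathy to CHD", 0.028, 0.016, 0.043, "beta"),
    # Annual / initial costs, 2007 US$
    row("c_blindness", "cost", "Blindness and retinopathy cost", 9912, 7251, 12945, "gamma"),
    row("c_cgm_annual", "cost", "CGM technology annual cost", 4189, 3062, 5492, "gamma"),
    row("c_cgm_initial", "cost", "Initial cost of CGM technology", 4809, 3499, 6321, "gamma"),
    row("c_chd", "cost", "CHD cost", 35271, 25820, 46433, "gamma"),
    row("c_base", "cost", "Diabetes with no complications cost", 6705, 4879, 8788, "gamma"),
    row("c_esrd", "cost", "ESRD cost", 36370, 26377, 47708, "gamma"),
    row("c_lea", "cost", "LEA cost", 50150, 36541, 65798, "gamma"),
    row("c_nephropathy", "cost", "Nephropathy cost", 20161, 14614, 26643, "gamma"),
    row("c_neuropathy", "cost", "Neuropathy cost", 25075, 18226, 33004, "gamma"),
    row("c_retinopathy", "cost", "Retinopathy cost", 4956, 3578, 6489, "gamma"),
    # EQ-5D utilities at age 40
    row("u_blindness", "utility", "Utility of blindness", 0.569, 0.531, 0.607, "beta"),
    row("u_chd", "utility", "Utility of CHD", 0.552, 0.513, 0.591, "beta"),
    row("u_esrd", "utility", "Utility of ESRD", 0.521, 0.485, 0.558, "beta"),
    row("u_lea", "utility", "Utility of LEA", 0.572, 0.538, 0.604, "beta"),
    row("u_nephropathy", "utility", "Utility of nephropathy", 0.575, 0.545, 0.606, "beta"),
    row("u_nephropathy_chd", "utility", "Utility of nephropathy and CHD", 0.516, 0.465, 0.567, "beta"),
    row("u_neuropathy", "utility", "Utility of neuropathy", 0.603, 0.573, 0.632, "beta"),
    row("u_neuropathy_chd", "utility", "Utility of neuropathy and CHD", 0.544, 0.495, 0.593, "beta"),
    row("u_neuropathy_nephropathy", "utility", "Utility of neuropathy and nephropathy", 0.557, 0.520, 0.595, "beta"),
    row("u_no_complications", "utility", "Utility of diabetes with no complications", 0.757, 0.747, 0.767, "beta"),
    row("u_retinopathy", "utility", "Utility of retinopathy", 0.612, 0.581, 0.643, "beta"),
    row("u_retinopathy_chd", "utility", "Utility of retinopathy and CHD", 0.553, 0.503, 0.605, "beta"),
    row("u_age_slope", "utility", "Disutility of age", -0.0003, family = "fixed"),
    # CGM relative risk reductions (from a 0.5% A1c reduction)
    row("rrr_chd", "risk_reduction", "CGM risk reduction for CHD", 0.050, 0.013, 0.107, "beta"),
    row("rrr_nephropathy", "risk_reduction", "CGM risk reduction for nephropathy", 0.270, 0.006, 0.768, "beta"),
    row("rrr_neuropathy", "risk_reduction", "CGM risk reduction for neuropathy", 0.188, 0.004, 0.593, "beta"),
    row("rrr_retinopathy", "risk_reduction", "CGM risk reduction for retinopathy", 0.306, 0.075, 0.618, "beta"),
    # Fixed model settings
    row("start_age", "setting", "Start age", 40, family = "fixed"),
    row("years_since_diagnosis", "setting", "Years since diagnosis", 20, family = "fixed"),
    row("discount_rate", "setting", "Discount rate", 0.03, family = "fixed"),
    row("horizon", "setting", "Time horizon (cycles)", 33, family = "fixed")
  )
})

#' Default parameter table
#'
#' The complete set of model inputs: 12 annual transition probabilities,
#' 10 cost parameters (2007 US$), 12 state utilities plus the fixed age
#' disutility slope, 4 CGM relative risk reductions, and the fixed settings
#' (start age 40, 20 years since diagnosis, 3\% discount rate, 33-year
#' horizon). Uncertain parameters carry 2.5\%/97.5\% credible bounds and the
#' distribution family used by the probabilistic sensitivity analysis (beta
#' for probabilities, utilities and risk reductions; gamma for costs).
#'
#' @return A data frame with columns `name`, `group`
#'   (`probability|cost|utility|risk_reduction|setting`), `label`, `mean`,
#'   `lo`, `hi`, `family`.
#' @examples
#' tbl <- default_parameter_table()
#' subset(tbl, group == "risk_reduction")
#' @export
default_parameter_table <- function() .PARAM_TABLE

#' Write / read a parameter table as CSV
#'
#' Round-trips the parameter table through a plain CSV with columns
#' `name, group, label, mean, lo, hi, family`, so users can edit inputs
#' outside R and feed them back to the model.
#'
#' @param table A parameter table as returned by [default_parameter_table()].
#' @param file Path to a CSV file.
#' @return `read_parameter_table()` returns a validated parameter table.
#' @export
write_parameter_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(file) {
  tbl <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("name", "group", "mean", "lo", "hi", "family")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop("parameter table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"label" %in% names(tbl)) tbl$label <- tbl$name
  bad <- setdiff(tbl$family, c("beta", "gamma", "fixed"))
  if (length(bad) > 0L) {
    stop("unknown distribution family: ", paste(unique(bad), collapse = ", "))
  }
  ranged <- tbl$family != "fixed"
  viol <- ranged & !(tbl$lo <= tbl$mean & tbl$mean <= tbl$hi)
  if (any(viol, na.rm = TRUE)) {
    stop("lo <= mean <= hi violated for: ",
         paste(tbl$name[which(viol)], collapse = ", "))
  }
  tbl[, c("name", "group", "label", "mean", "lo", "hi", "family")]
}

.param_values <- function(table = default_parameter_table()) {
  stats::setNames(table$mean, table$name)
}

# Marginal annual cost of each living state, derived from the drawn cost
# primitives. Composite states sum their components' marginals; blindness,
# ESRD and LEA carry their own single marginal.
.state_marginal_costs <- function(v) {
  c(
    no_complications       = 0,
    retinopathy            = unname(v["c_retinopathy"]),
    nephropathy            = unname(v["c_nephropathy"]),
    neuropathy             = unname(v["c_neuropathy"]),
    chd                    = unname(v["c_chd"]),
    blindness              = unname(v["c_blindness"]),
    esrd                   = unname(v["c_esrd"]),
    lea                    = unname(v["c_lea"]),
    nephropathy_chd        = unname(v["c_nephropathy"] + v["c_chd"]),
    neuropathy_chd         = unname(v["c_neuropathy"] + v["c_chd"]),
    retinopathy_chd        = unname(v["c_retinopathy"] + v["c_chd"]),
    neuropathy_nephropathy = unname(v["c_neuropathy"] + v["c_nephropathy"])
  )
}

.state_utilities <- function(v) {
  c(
    no_complications       = unname(v["u_no_complications"]),
    retinopathy            = unname(v["u_retinopathy"]),
    nephropathy            = unname(v["u_nephropathy"]),
    neuropathy             = unname(v["u_neuropathy"]),
    chd                    = unname(v["u_chd"]),
    blindness              = unname(v["u_blindness"]),
    esrd                   = unname(v["u_esrd"]),
    lea                    = unname(v["u_lea"]),
    nephropathy_chd        = unname(v["u_nephropathy_chd"]),
    neuropathy_chd         = unname(v["u_neuropathy_chd"]),
    retinopathy_chd        = unname(v["u_retinopathy_chd"]),
    neuropathy_nephropathy = unname(v["u_neuropathy_nephropathy"])
  )
}

#' Assemble a complete model parameter set
#'
#' Builds the structured parameter object the cohort engine consumes from a
#' named vector of input values (defaulting to the point estimates of
#' [default_parameter_table()]). Composite-state annual costs are recomputed
#' by summing the component marginals (nephropathy+CHD, neuropathy+CHD,
#' retinopathy+CHD, neuropathy+nephropathy); composite-state utilities are
#' taken from their own rows. Overrides for individual inputs can be passed
#' via `...` (e.g. `model_parameters(discount_rate = 0)`).
#'
#' @param values Named numeric vector of parameter values; names must match
#'   the parameter table. Defaults to the point estimates.
#' @param ... Named scalar overrides applied on top of `values`.
#' @return An object of class `cea_parameters`: transition probabilities,
#'   per-state annual costs and utilities, CGM costs, risk reductions,
#'   discounting and horizon settings.
#' @examples
#' p <- model_parameters()
#' p$risk_reductions
#' @export
model_parameters <- function(values = NULL, ...) {
  v <- .param_values()
  if (!is.null(values)) {
    unknown <- setdiff(names(values), names(v))
    if (length(unknown) > 0L) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    v[names(values)] <- values
  }
  dots <- list(...)
  if (length(dots) > 0L) {
    unknown <- setdiff(names(dots), names(v))
    if (length(unknown) > 0L) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    v[names(dots)] <- unlist(dots)
  }

  probs <- v[startsWith(names(v), "p_")]
  if (any(probs < 0 | probs > 1)) {
    stop("transition probabilities outside [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  rrr <- c(
    retinopathy = unname(v["rrr_retinopathy"]),
    nephropathy = unname(v["rrr_nephropathy"]),
    neuropathy  = unname(v["rrr_neuropathy"]),
    chd         = unname(v["rrr_chd"])
  )
  if (any(rrr < 0 | rrr > 1)) {
    stop("risk reductions outside [0, 1]")
  }
  utils_ <- .state_utilities(v)
  if (any(utils_ < 0 | utils_ > 1)) {
    stop("state utilities outside [0, 1]")
  }
  costs <- .state_marginal_costs(v)
  if (any(costs < 0) || v["c_base"] < 0 || v["c_cgm_annual"] < 0 ||
      v["c_cgm_initial"] < 0) {
    stop("costs must be non-negative")
  }
  if (v["horizon"] < 0) stop("horizon must be >= 0 cycles")
  if (v["discount_rate"] < 0) stop("discount rate must be >= 0")

  structure(
    list(
      transition_probs = probs,
      state_marginal_costs = costs,
      base_annual_cost = unname(v["c_base"]),
      cgm_initial_cost = unname(v["c_cgm_initial"]),
      cgm_annual_cost = unname(v["c_cgm_annual"]),
      utilities = utils_,
      age_disutility_per_year = unname(v["u_age_slope"]),
      risk_reductions = rrr,
      discount_rate = unname(v["discount_rate"]),
      start_age = unname(v["start_age"]),
      horizon = as.integer(v["horizon"]),
      subsequent_lea_prob = unname(v["p_subsequent_lea"]),
      values = v
    ),
    class = "cea_parameters"
  )
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Type 1 diabetes cost-utility model parameters\n")
  cat(sprintf("  start age %g, horizon %d one-year cycles, discount %.1f%%\n",
              x$start_age, x$horizon, 100 * x$discount_rate))
  cat(sprintf("  base annual cost $%s; CGM initial $%s, annual $%s\n",
              format(x$base_annual_cost, big.mark = ","),
              format(x$cgm_initial_cost, big.mark = ","),
              format(x$cgm_annual_cost, big.mark = ",")))
  cat("  CGM relative risk reductions:",
      paste(sprintf("%s %.3f", names(x$risk_reductions), x$risk_reductions),
            collapse = ", "), "\n")
  invisible(x)
}
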