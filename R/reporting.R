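# Report assembly: CSV outputs mirroring the published result tables, plus a
# sidecar metadata file (seed, settings, config hash) for reproducibility.

# djb2-style rolling hash of a deparsed R object, kept within 31 bits so
# integer arithmetic stays exact; cheap fingerprint for sidecar metadata.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_sidecar <- function(dir, stem, config) {
  meta <- c(
    sprintf("config_hash: %s", .config_hash(config)),
    vapply(names(config), function(k) {
      sprintf("%s: %s", k, paste(format(config[[k]]), collapse = " "))
    }, character(1))
  )
  writeLines(meta, file.path(dir, paste0(stem, "_meta.txt")))
}

.ensure_dir <- function(dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  dir
}

#' Write the base-case report
#'
#' One row per arm (discounted cost, QALYs, life-years) plus an incremental
#' row (delta cost, delta QALYs, ICER), in the layout of a standard
#' cost-effectiveness results table; optionally the full cycle-by-state
#' occupancy traces. A sidecar metadata file records the run configuration.
#'
#' @param base_case A `base_case` from [run_base_case()].
#' @param dir Output directory (created if missing).
#' @param write_trace Also write `trace_smbg.csv` / `trace_cgm.csv`.
#' @param config Named list recorded in the sidecar (seed, mortality source,
#'   ...).
#' @return Invisibly, the path of the main results CSV.
#' @export
write_base_case_report <- function(base_case, dir, write_trace = FALSE,
                                   config = list()) {
  .ensure_dir(dir)
  ce <- base_case$ce
  df <- data.frame(
    row = c("smbg", "cgm", "incremental"),
    cost = c(base_case$smbg$discounted_cost, base_case$cgm$discounted_cost,
             ce$delta_cost),
    qalys = c(base_case$smbg$discounted_qalys, base_case$cgm$discounted_qalys,
              ce$delta_effect),
    life_years = c(base_case$smbg$life_years, base_case$cgm$life_years, NA),
    icer = c(NA, NA, ce$icer),
    dominance = c(NA, NA, ce$dominance),
    stringsAsFactors = FALSE
  )
  path <- file.path(dir, "base_case.csv")
  utils::write.csv(df, path, row.names = FALSE)
  if (write_trace) {
    for (arm in c("smbg", "cgm")) {
      tr <- base_case[[arm]]$trace
      utils::write.csv(
        data.frame(cycle = as.integer(rownames(tr)), tr, check.names = FALSE),
        file.path(dir, paste0("trace_", arm, ".csv")), row.names = FALSE)
    }
  }
  .write_sidecar(dir, "base_case", config)
  invisible(path)
}

#' Write the PSA report
#'
#' Writes the per-iteration scatter (arm costs/QALYs and increments), the
#' cost-effectiveness acceptability curve over a willingness-to-pay grid, and
#' a quadrant/cost-effectiveness summary at each requested threshold.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param dir Output directory.
#' @param wtp Thresholds (US$/QALY) summarised in `psa_summary.csv`.
#' @param wtp_grid Grid for the acceptability curve.
#' @param config Named list recorded in the sidecar.
#' @return Invisibly, the path of the scatter CSV.
#' @export
write_psa_report <- function(psa, dir, wtp = c(50000, 100000),
                             wtp_grid = seq(0, 200000, by = 5000),
                             config = list()) {
  .ensure_dir(dir)
  scatter <- cbind(iteration = seq_len(psa$n_iterations), psa$draws)
  utils::write.csv(scatter, file.path(dir, "psa_scatter.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(psa, wtp_grid), file.path(dir, "psa_ceac.csv"),
                   row.names = FALSE)
  summ <- do.call(rbind, lapply(wtp, function(w) {
    fr <- quadrant_fractions(psa, w)
    data.frame(wtp = w, t(fr))
  }))
  utils::write.csv(summ, file.path(dir, "psa_summary.csv"), row.names = FALSE)
  .write_sidecar(dir, "psa",
                 c(config, list(seed = psa$seed, n = psa$n_iterations)))
  invisible(file.path(dir, "psa_scatter.csv"))
}

#' Write the tornado report
#'
#' Writes the full ranked tornado table, a top-`n_top` extract, and (when a
#' mortality schedule is supplied) a probe table giving the full incremental
#' result with each top parameter multiplied by `1 - probe_pct` and
#' `1 + probe_pct`.
#'
#' @param torn A `tornado_result` from [tornado()].
#' @param dir Output directory.
#' @param n_top Number of leading parameters in the extract and probe tables.
#' @param probe_pct Probe perturbation fraction (default 0.5).
#' @param table,mortality Inputs forwarded to [probe_icer()]; probes are
#'   skipped when `mortality` is missing.
#' @param config Named list recorded in the sidecar.
#' @return Invisibly, the path of the full tornado CSV.
#' @export
write_tornado_report <- function(torn, dir, n_top = 10, probe_pct = 0.5,
                                 table = default_parameter_table(),
                                 mortality = NULL, config = list()) {
  .ensure_dir(dir)
  full <- as.data.frame(torn)
  full$rank <- seq_len(nrow(full))
  utils::write.csv(full, file.path(dir, "tornado.csv"), row.names = FALSE)
  top <- utils::head(full, n_top)
  utils::write.csv(top, file.path(dir, "tornado_top.csv"), row.names = FALSE)
  if (!is.null(mortality)) {
    probes <- do.call(rbind, lapply(top$parameter, function(pname) {
      do.call(rbind, lapply(c(1 - probe_pct, 1 + probe_pct), function(f) {
        ce <- probe_icer(pname, f, table = table, mortality = mortality)
        data.frame(parameter = pname, factor = f,
                   delta_cost = ce$delta_cost, delta_effect = ce$delta_effect,
                   icer = ce$icer, dominance = ce$dominance,
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(probes, file.path(dir, "tornado_probes.csv"),
                     row.names = FALSE)
  }
  .write_sidecar(dir, "tornado",
                 c(config, list(wtp = attr(torn, "wtp"),
                                pct = attr(torn, "pct"))))
  invisible(file.path(dir, "tornado.csv"))
}
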