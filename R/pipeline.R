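#' Study run configuration
#'
#' Bundles everything [run_study()] needs: cohort generator settings, the
#' population model, the scenario list, the harmonization toggle, acceptance
#' thresholds and a single global seed from which all per-stage seeds are
#' derived.
#'
#' @param cohort a [cohort_config()]; its seed is overridden by `seed`.
#' @param pop a [population_model()].
#' @param scenarios named list of [scenario_spec()]s.
#' @param harmonize logical; when `TRUE` the combined-method (population B)
#'   scenarios are additionally evaluated with all inputs adjusted to the
#'   target measurement's scale.
#' @param thresholds an [acceptance_thresholds()].
#' @param seed global integer seed.
#' @return List of class `bili_run_config`.
#' @export
run_config <- function(cohort = cohort_config(), pop = population_model(),
                       scenarios = default_scenarios(), harmonize = TRUE,
                       thresholds = acceptance_thresholds(),
                       seed = 20260917) {
  ids <- vapply(scenarios, function(s) s$scenario_id, integer(1))
  if (anyDuplicated(ids)) stop("scenario ids must be unique")
  cohort$seed <- as.integer(child_seed(seed, 1))
  structure(list(cohort = cohort, pop = pop, scenarios = scenarios,
                 harmonize = isTRUE(harmonize), thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "bili_run_config")
}

predict_instances <- function(inst_list, spec, cohort, pop,
                              harmonize_inputs = FALSE, offset = 14.3) {
  pat <- cohort$patients
  rows <- vector("list", length(inst_list))
  for (i in seq_along(inst_list)) {
    ins <- inst_list[[i]]
    prow <- pat[pat$patient_id == ins$patient_id, ]
    cov <- covariates(prow$ga_weeks, prow$birth_weight_g, prow$sex,
                      prow$delivery_mode, prow$hemolytic)
    inputs <- as_measurements(ins$inputs)
    b_last <- inputs$value[which.max(inputs$pna)]
    if (harmonize_inputs) {
      inputs <- harmonize(inputs, ins$target$method, offset)
      b_last <- inputs$value[which.max(inputs$pna)]
    }
    b_pred <- predict_bilirubin(pop, cov, inputs, ins$t_target,
                                horizon_limit = spec$horizon)
    rows[[i]] <- data.frame(
      patient_id = ins$patient_id, scenario_id = spec$scenario_id,
      b_pred = b_pred, b_obs = ins$target$value, b_last = b_last,
      t_last = ins$t_last, t_target = ins$t_target,
      target_method = ins$target$method,
      hemolytic = prow$hemolytic, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), scenario_id = integer(0),
               b_pred = numeric(0), b_obs = numeric(0), b_last = numeric(0),
               t_last = numeric(0), t_target = numeric(0),
               target_method = character(0), hemolytic = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Observed vs predicted bilirubin increase-rate summaries
#'
#' Computes the rate of increase twice per record — once with the observed
#' target value, once with the predicted one — and returns median and IQR of
#' each (mg/dl per hour).
#'
#' @param records prediction-record data frame with columns `b_obs`,
#'   `b_pred`, `b_last`, `t_target`, `t_last`.
#' @return List with `observed` and `predicted`, each `c(median, q1, q3)`,
#'   and `n`.
#' @export
compare_increase_rates <- function(records) {
  if (!nrow(records)) stop("no prediction records supplied")
  q <- function(x) setNames(unname(quantile(x, c(0.5, 0.25, 0.75), type = 7)),
                            c("median", "q1", "q3"))
  obs <- increase_rate(records$b_obs, records$b_last,
                       records$t_target, records$t_last)
  prd <- increase_rate(records$b_pred, records$b_last,
                       records$t_target, records$t_last)
  list(observed = q(obs), predicted = q(prd), n = nrow(records))
}

#' Run the complete validation study on a synthetic cohort
#'
#' Executes all stages in order: cohort generation, scenario construction,
#' prediction (for combined-method scenarios in both the
#' measurement-type-adjusted and unadjusted arms when harmonization is on),
#' validation summaries, hemolytic-subgroup re-analysis of the pure
#' scenarios, and observed-vs-predicted increase-rate comparison for the
#' combined scenarios. Fully deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param dir optional output directory; when given, writes `patients.csv`,
#'   `measurements.csv`, `scenario_instances.csv`, `predictions.csv`,
#'   `summary.json` and `report.md`.
#' @return List of class `bili_run_report` with elements `summaries` (per
#'   scenario/arm), `hemolytic` (per pure scenario, or `"empty"` marker),
#'   `increase_rates`, `accounting`, `predictions` (data frame with an `arm`
#'   column) and `cohort`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_study(run_config(cohort = cohort_config(n_patients = 40),
#'                             seed = 1))
#' rep$summaries$s2
#' }
run_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "bili_run_config"))
  pop <- config$pop
  cohort <- generate_cohort(config$cohort, pop)
  pops <- build_population(cohort, config$scenarios)

  offset <- config$cohort$tcb_offset %||% pop$tcb_offset
  preds <- list()
  summaries <- list()
  hemolytic <- list()
  increase_rates <- list()
  for (nm in names(config$scenarios)) {
    spec <- config$scenarios[[nm]]
    inst <- pops$instances[[nm]]
    arms <- if (spec$population == "B" && config$harmonize)
      c("adjusted", "unadjusted")
    else if (spec$population == "B") "unadjusted" else "primary"
    for (arm in arms) {
      rec <- predict_instances(inst, spec, cohort, pop,
                               harmonize_inputs = (arm == "adjusted"),
                               offset = offset)
      rec$arm <- rep(arm, nrow(rec))
      key <- if (spec$population == "B") paste(nm, arm, sep = "_") else nm
      preds[[key]] <- rec
      summaries[[key]] <- if (nrow(rec) >= 2)
        summarize_validation(rec, config$thresholds) else "empty"
      if (spec$population == "B" && nrow(rec) >= 1)
        increase_rates[[key]] <- compare_increase_rates(rec)
      if (spec$population == "A") {
        sub <- rec[rec$hemolytic, , drop = FALSE]
        hemolytic[[nm]] <- if (nrow(sub) >= 2)
          summarize_validation(sub, config$thresholds) else "empty"
      }
    }
  }
  predictions <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  report <- structure(list(summaries = summaries, hemolytic = hemolytic,
                           increase_rates = increase_rates,
                           accounting = pops$accounting,
                           predictions = predictions,
                           cohort = cohort, populations = pops,
                           config = config),
                      class = "bili_run_report")
  if (!is.null(dir)) write_run_report(report, dir)
  report
}

summary_to_list <- function(s) {
  if (identical(s, "empty")) return(list(status = "empty"))
  list(n = s$n, margin_95ci = s$margin_95ci,
       median_iqr_ape = as.list(s$median_iqr_ape),
       median_iqr_rpe = as.list(s$median_iqr_rpe),
       n_under = s$n_under, pct_under = s$pct_under,
       n_over = s$n_over, pct_over = s$pct_over,
       clinical_acceptance = s$clinical_acceptance,
       exactness = s$exactness)
}

#' Write a run report to disk
#'
#' Emits the cohort CSVs, scenario instances, per-arm predictions, a
#' `summary.json` holding every validation summary (plus hemolytic subgroup,
#' increase rates and CONSORT accounting), and a human-readable `report.md`
#' mirroring the per-scenario result tables.
#'
#' @param report a `bili_run_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, dir)
  instances_table(report$populations, file.path(dir, "scenario_instances.csv"))
  pr <- report$predictions
  pr$pe <- prediction_error(pr$b_pred, pr$b_obs)
  pr$ape <- abs(pr$pe)
  pr$rpe_pct <- relative_prediction_error(pr$b_pred, pr$b_obs)
  write.csv(pr, file.path(dir, "predictions.csv"), row.names = FALSE,
            quote = FALSE)
  doc <- list(seed = report$config$seed,
              summaries = lapply(report$summaries, summary_to_list),
              hemolytic = lapply(report$hemolytic, summary_to_list),
              increase_rates = report$increase_rates,
              accounting = report$accounting)
  jsonlite::write_json(doc, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(dir, "report.md"))
  invisible(dir)
}

render_report_md <- function(report) {
  fmt_s <- function(key, s) {
    if (identical(s, "empty"))
      return(sprintf("| %s | (empty) | | | |", key))
    sprintf("| %s | %d | %.1f | %.1f%% (%.1f, %.1f) | under %d (%.1f%%) / over %d (%.1f%%) |",
            key, s$n, s$margin_95ci, s$median_iqr_rpe[1], s$median_iqr_rpe[2],
            s$median_iqr_rpe[3], s$n_under, s$pct_under, s$n_over, s$pct_over)
  }
  lines <- c("# Validation run report", "",
             "## Per-scenario validation summaries", "",
             "| scenario/arm | n | margin of 95% CI (umol/L) | median (IQR) rPE | mis-predictions |",
             "|---|---|---|---|---|",
             unlist(Map(fmt_s, names(report$summaries), report$summaries)),
             "", "## Hemolytic subgroup (pure scenarios)", "",
             "| scenario | n | margin of 95% CI (umol/L) | median (IQR) rPE | mis-predictions |",
             "|---|---|---|---|---|",
             unlist(Map(fmt_s, names(report$hemolytic), report$hemolytic)))
  if (length(report$increase_rates)) {
    fmt_r <- function(key, r) {
      sprintf("| %s | %d | %.2f (%.3f, %.2f) | %.2f (%.3f, %.2f) |",
              key, r$n, r$observed[1], r$observed[2], r$observed[3],
              r$predicted[1], r$predicted[2], r$predicted[3])
    }
    lines <- c(lines, "", "## Bilirubin increase rates (mg/dl per hour)", "",
               "| scenario/arm | n | observed median (IQR) | predicted median (IQR) |",
               "|---|---|---|---|",
               unlist(Map(fmt_r, names(report$increase_rates),
                          report$increase_rates)))
  }
  acct <- report$accounting
  lines <- c(lines, "", "## CONSORT-style accounting", "",
             paste0("| ", paste(names(acct), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(acct)), collapse = "|"), "|"),
             apply(acct, 1, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")))
  lines
}
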