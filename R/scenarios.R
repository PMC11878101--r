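#' Validation scenario specification
#'
#' A scenario fixes the number of input measurements, the methods allowed for
#' them, the prediction horizon, and the postnatal-age windows and spacing
#' rules used to pick inputs and target out of a longitudinal record:
#' \itemize{
#'   \item the first input must fall between 8 and 72 h of postnatal age;
#'   \item each further input is the first measurement at least 8 h after the
#'     previous one and inside the subsequent window (24-96 h for the pure
#'     scenarios, population A; 24-120 h for the combined scenarios,
#'     population B);
#'   \item the target is the last eligible measurement (>= 8 h after the last
#'     input, inside the subsequent window) whose distance from the last
#'     input does not exceed the horizon;
#'   \item when two measurements share a time point and both methods are
#'     allowed, the TcB reading is chosen (pressure testing with the noisier
#'     method).
#' }
#' All window boundaries are closed.
#'
#' @param scenario_id integer 1-5.
#' @param n_inputs number of input measurements (1-3).
#' @param methods character subset of `c("TSB", "TcB")` allowed for inputs
#'   and target.
#' @param horizon prediction horizon, hours (30, 48 or 60).
#' @param population `"A"` (subsequent window 24-96 h) or `"B"` (24-120 h).
#' @return An object of class `bili_scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, n_inputs, methods, horizon,
                          population = c("A", "B")) {
  population <- match.arg(population)
  if (!horizon %in% c(30, 48, 60)) stop("horizon must be 30, 48 or 60 h")
  if (!n_inputs %in% 1:3) stop("n_inputs must be 1, 2 or 3")
  if (!all(methods %in% c("TSB", "TcB")) || !length(methods))
    stop("methods must be a non-empty subset of TSB, TcB")
  structure(list(scenario_id = as.integer(scenario_id),
                 n_inputs = as.integer(n_inputs),
                 methods = methods, horizon = horizon,
                 population = population,
                 first_window = c(8, 72),
                 subsequent_window = if (population == "A") c(24, 96)
                                     else c(24, 120),
                 min_gap = 8),
            class = "bili_scenario_spec")
}

#' The five standard validation scenarios
#'
#' Scenario 1: one TSB, 30 h. Scenario 2: two TSB, 60 h. Scenario 3: three
#' TcB, 48 h (population A). Scenario 4: any two measurements, 48 h.
#' Scenario 5: any three measurements, 48 h (population B, windows extended
#' to 120 h).
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  list(
    s1 = scenario_spec(1, 1, "TSB", 30, "A"),
    s2 = scenario_spec(2, 2, "TSB", 60, "A"),
    s3 = scenario_spec(3, 3, "TcB", 48, "A"),
    s4 = scenario_spec(4, 2, c("TSB", "TcB"), 48, "B"),
    s5 = scenario_spec(5, 3, c("TSB", "TcB"), 48, "B"))
}

# order measurements chronologically with TcB before TSB at shared times,
# so a greedy forward scan realizes the tie rule
order_for_scan <- function(m) {
  m[order(m$pna, m$method != "TcB"), , drop = FALSE]
}

#' Select scenario inputs and target from one patient's record
#'
#' Applies the rule set of a [scenario_spec()] to a chronologically sorted
#' measurement record. Selection is greedy and deterministic: the first
#' eligible measurement fills each input slot, and the latest eligible
#' measurement within the horizon is the target.
#'
#' @param measurements a [bili_measurements()] set (sorted by `pna`).
#' @param spec a [scenario_spec()].
#' @return A list with `accepted` (logical) and either `instance` (a list
#'   with `inputs`, `target`, `t_last`, `t_target`, `horizon_used`) or
#'   `reason`, one of `"no_first_measurement"`, `"first_window"`,
#'   `"input_gap_window"`, `"no_target"`, `"target_horizon"`.
#' @export
select_inputs <- function(measurements, spec) {
  stopifnot(inherits(spec, "bili_scenario_spec"))
  m <- as_measurements(measurements)
  if (is.unsorted(m$pna)) stop("measurements must be sorted by pna")
  m <- order_for_scan(m)
  allowed <- m$method %in% spec$methods

  reject <- function(reason) list(accepted = FALSE, reason = reason)

  # first input: first allowed measurement inside the first window
  cand1 <- which(allowed & m$pna >= spec$first_window[1] &
                   m$pna <= spec$first_window[2])
  if (!length(cand1)) {
    if (!any(allowed)) return(reject("no_first_measurement"))
    return(reject("first_window"))
  }
  idx <- cand1[1]
  chosen <- idx
  # subsequent inputs
  if (spec$n_inputs > 1) {
    for (k in 2:spec$n_inputs) {
      prev_t <- m$pna[chosen[length(chosen)]]
      cand <- which(allowed &
                      m$pna >= prev_t + spec$min_gap &
                      m$pna >= spec$subsequent_window[1] &
                      m$pna <= spec$subsequent_window[2])
      cand <- setdiff(cand, chosen)
      if (!length(cand)) return(reject("input_gap_window"))
      chosen <- c(chosen, cand[1])
    }
  }
  t_last <- m$pna[chosen[length(chosen)]]

  # target: eligible = allowed method, >= 8 h after last input, in window
  elig <- which(allowed &
                  m$pna >= t_last + spec$min_gap &
                  m$pna >= spec$subsequent_window[1] &
                  m$pna <= spec$subsequent_window[2])
  elig <- setdiff(elig, chosen)
  if (!length(elig)) return(reject("no_target"))
  within <- elig[m$pna[elig] - t_last <= spec$horizon]
  if (!length(within)) return(reject("target_horizon"))
  # last measurement within the horizon; TcB-first ordering breaks ties
  tgt <- within[which.max(m$pna[within])]

  inputs <- m[chosen, , drop = FALSE]
  rownames(inputs) <- NULL
  list(accepted = TRUE,
       instance = list(inputs = inputs,
                       target = m[tgt, , drop = FALSE],
                       t_last = t_last,
                       t_target = m$pna[tgt],
                       horizon_used = m$pna[tgt] - t_last))
}

#' Build scenario populations from a cohort
#'
#' Runs [select_inputs()] for every patient and scenario, collecting accepted
#' instances and a CONSORT-style accounting of rejections per rule. A patient
#' may contribute to several scenarios.
#'
#' @param cohort a `bili_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param specs list of [scenario_spec()]s; default [default_scenarios()].
#' @return A list of class `bili_scenario_populations` with `instances` (per
#'   spec, a list of patient instances) and `accounting` (data frame:
#'   scenario_id, n_patients, n_accepted and one column per rejection
#'   reason).
#' @export
build_population <- function(cohort, specs = default_scenarios()) {
  pat_ids <- cohort$patients$patient_id
  reasons <- c("no_first_measurement", "first_window", "input_gap_window",
               "no_target", "target_horizon")
  instances <- vector("list", length(specs))
  names(instances) <- names(specs)
  acct <- NULL
  meas_split <- split(cohort$measurements, cohort$measurements$patient_id)
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    inst <- list()
    counts <- setNames(numeric(length(reasons)), reasons)
    for (pid in pat_ids) {
      mi <- meas_split[[pid]]
      if (is.null(mi) || nrow(mi) == 0) {
        counts["no_first_measurement"] <- counts["no_first_measurement"] + 1
        next
      }
      m <- bili_measurements(mi$pna_h, mi$value_umol_l, mi$method)
      res <- select_inputs(m, spec)
      if (res$accepted) {
        res$instance$patient_id <- pid
        res$instance$scenario_id <- spec$scenario_id
        inst[[length(inst) + 1L]] <- res$instance
      } else {
        counts[res$reason] <- counts[res$reason] + 1
      }
    }
    instances[[s]] <- inst
    acct <- rbind(acct, data.frame(scenario_id = spec$scenario_id,
                                   n_patients = length(pat_ids),
                                   n_accepted = length(inst),
                                   t(counts), stringsAsFactors = FALSE))
  }
  rownames(acct) <- NULL
  structure(list(instances = instances, accounting = acct, specs = specs),
            class = "bili_scenario_populations")
}

#' Flatten scenario instances to a data frame / CSV
#'
#' One row per instance: scenario_id, patient_id, semicolon-joined input
#' times, values and methods, the target, and the realized horizon.
#'
#' @param pops a `bili_scenario_populations`.
#' @param path optional CSV path.
#' @return Data frame (invisibly writes `path` when given).
#' @export
instances_table <- function(pops, path = NULL) {
  rows <- list()
  for (inst_list in pops$instances) {
    for (ins in inst_list) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_id = ins$scenario_id, patient_id = ins$patient_id,
        input_pnas = paste(sprintf("%.3f", ins$inputs$pna), collapse = ";"),
        input_values = paste(sprintf("%.3f", ins$inputs$value), collapse = ";"),
        input_methods = paste(ins$inputs$method, collapse = ";"),
        target_pna = ins$t_target, target_value = ins$target$value,
        target_method = ins$target$method,
        horizon_used_h = ins$horizon_used, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario_id = integer(0), patient_id = character(0),
               input_pnas = character(0), input_values = character(0),
               input_methods = character(0), target_pna = numeric(0),
               target_value = numeric(0), target_method = character(0),
               horizon_used_h = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
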