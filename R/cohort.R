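#' Configuration of the synthetic neonatal cohort generator
#'
#' Defines demographic targets, sampling-schedule policy and measurement-error
#' overrides for [generate_cohort()]. Default demographic targets follow the
#' pooled characteristics of a late-preterm/term nursery population:
#' gestational age median 38.7 weeks with quartiles (37.0, 39.9), birth
#' weight median 3155 g with quartiles (2670, 3510), about 39% female and
#' 35% cesarean deliveries. Gestational age and weight are drawn from
#' half-normal mixtures around the median (a cheap skewed family that hits a
#' median and both quartiles exactly before truncation), truncated to the
#' inclusion rules (GA >= 34 weeks, weight >= 1500 g).
#'
#' The schedule policy places a first measurement at 20-52 h of postnatal age
#' and subsequent measurements at gaps of 12-36 h, 3-6 measurements per
#' neonate, all within 120 h, emulating routine pre-discharge bilirubin
#' monitoring. Measurement methods follow a per-patient monitoring style: a
#' neonate is "TcB-monitored" with probability `p_tcb_patient`, and each
#' individual reading is then transcutaneous with probability
#' `p_tcb_within[1]` (TcB-monitored) or `p_tcb_within[2]` (TSB-monitored).
#' This yields the mix of pure-TSB, pure-TcB and combined records that the
#' validation scenarios require.
#'
#' @param n_patients number of neonates.
#' @param seed integer seed; the generator is fully reproducible given it.
#' @param ga_median,ga_q1,ga_q3 gestational-age targets, weeks.
#' @param wt_median,wt_q1,wt_q3 birth-weight targets, grams.
#' @param p_female,p_cesarean,p_hemolytic marginal proportions in `[0, 1]`.
#' @param first_window earliest/latest postnatal age of the first
#'   measurement, hours.
#' @param gap_range min/max gap between consecutive measurements, hours.
#' @param n_meas_range min/max number of measurements per neonate.
#' @param max_pna latest allowed measurement time, hours.
#' @param p_tcb_patient probability a neonate is TcB-monitored.
#' @param p_tcb_within length-2 vector: per-reading TcB probability for
#'   TcB-monitored and TSB-monitored neonates.
#' @param tcb_offset,sigma_tsb,sigma_tcb optional overrides of the
#'   measurement-error model; `NULL` uses the population model's values.
#' @return An object of class `bili_cohort_config`.
#' @export
cohort_config <- function(n_patients = 276, seed = 20260917,
                          ga_median = 38.7, ga_q1 = 37.0, ga_q3 = 39.9,
                          wt_median = 3155, wt_q1 = 2670, wt_q3 = 3510,
                          p_female = 0.39, p_cesarean = 0.35,
                          p_hemolytic = 0.08,
                          first_window = c(20, 52),
                          gap_range = c(12, 36),
                          n_meas_range = c(3, 6),
                          max_pna = 120,
                          p_tcb_patient = 0.45,
                          p_tcb_within = c(0.85, 0.15),
                          tcb_offset = NULL, sigma_tsb = NULL,
                          sigma_tcb = NULL) {
  props <- c(p_female = p_female, p_cesarean = p_cesarean,
             p_hemolytic = p_hemolytic, p_tcb_patient = p_tcb_patient,
             p_tcb_within = p_tcb_within)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1))
    stop("proportions must lie in [0, 1]")
  if (n_patients < 0) stop("n_patients must be nonnegative")
  if (first_window[1] <= 0 || first_window[2] > 72)
    stop("first measurement window must lie within (0, 72] h")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 ga_median = ga_median, ga_q1 = ga_q1, ga_q3 = ga_q3,
                 wt_median = wt_median, wt_q1 = wt_q1, wt_q3 = wt_q3,
                 p_female = p_female, p_cesarean = p_cesarean,
                 p_hemolytic = p_hemolytic,
                 first_window = first_window, gap_range = gap_range,
                 n_meas_range = n_meas_range, max_pna = max_pna,
                 p_tcb_patient = p_tcb_patient, p_tcb_within = p_tcb_within,
                 tcb_offset = tcb_offset,
                 sigma_tsb = sigma_tsb, sigma_tcb = sigma_tcb),
            class = "bili_cohort_config")
}

# skewed draw with exact median m and quartiles (q1, q3) before truncation:
# a 50/50 mixture of half-normals below and above the median
rskewed <- function(n, m, q1, q3, lower = -Inf, upper = Inf) {
  z25 <- qnorm(0.75)  # half-normal median multiplier
  sd_l <- (m - q1) / z25
  sd_r <- (q3 - m) / z25
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    side <- runif(length(todo)) < 0.5
    draw <- m + ifelse(side, -abs(rnorm(length(todo), 0, sd_l)),
                       abs(rnorm(length(todo), 0, sd_r)))
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Sample neonate covariates
#'
#' Draws `config$n_patients` covariate records (with per-patient true random
#' effects from the population `omega`) matching the configured demographic
#' targets. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param pop a [population_model()] supplying `omega` for the true
#'   individual random effects.
#' @return A data frame with columns `patient_id`, `ga_weeks`,
#'   `birth_weight_g`, `sex`, `delivery_mode`, `hemolytic`, `eta1`, `eta2`
#'   (the last two are simulation truth, hidden from prediction).
#' @export
sample_covariates <- function(config, pop = population_model()) {
  stopifnot(inherits(config, "bili_cohort_config"))
  n <- config$n_patients
  empty <- data.frame(patient_id = character(0), ga_weeks = numeric(0),
                      birth_weight_g = numeric(0), sex = character(0),
                      delivery_mode = character(0), hemolytic = logical(0),
                      eta1 = numeric(0), eta2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  L <- chol_psd(pop$omega)
  # one child seed per patient: a patient's record is invariant to cohort
  # size and to the order patients are generated in
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- withr_seed(child_seed(config$seed, i), {
      eta <- drop(L %*% rnorm(2))
      data.frame(
        patient_id = sprintf("P%04d", i),
        ga_weeks = rskewed(1, config$ga_median, config$ga_q1, config$ga_q3,
                           lower = 34, upper = 43),
        birth_weight_g = rskewed(1, config$wt_median, config$wt_q1,
                                 config$wt_q3, lower = 1500, upper = 5500),
        sex = if (runif(1) < config$p_female) "female" else "male",
        delivery_mode = if (runif(1) < config$p_cesarean) "cesarean"
                        else "vaginal",
        hemolytic = runif(1) < config$p_hemolytic,
        eta1 = eta[1], eta2 = eta[2], stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# lower Cholesky factor tolerant of semi-definite omega
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v))
}

#' Sample a measurement schedule for one neonate
#'
#' Draws the number of measurements, the first time point inside the
#' configured first window, subsequent gaps inside the gap range (stopping at
#' `max_pna`), and a TSB/TcB label per time point. Deterministic given the
#' RNG state; [generate_cohort()] seeds per patient.
#'
#' @param config a [cohort_config()].
#' @return Data frame with columns `pna` (hours, sorted) and `method`.
#' @export
sample_schedule <- function(config) {
  stopifnot(inherits(config, "bili_cohort_config"))
  n_target <- sample(config$n_meas_range[1]:config$n_meas_range[2], 1)
  t <- runif(1, config$first_window[1], config$first_window[2])
  pna <- t
  while (length(pna) < n_target) {
    t <- t + runif(1, config$gap_range[1], config$gap_range[2])
    if (t > config$max_pna) break
    pna <- c(pna, t)
  }
  p_tcb <- if (runif(1) < config$p_tcb_patient) config$p_tcb_within[1]
           else config$p_tcb_within[2]
  method <- ifelse(runif(length(pna)) < p_tcb, "TcB", "TSB")
  data.frame(pna = pna, method = method, stringsAsFactors = FALSE)
}

#' Simulate bilirubin measurements along a schedule
#'
#' Evaluates the patient's true trajectory at the scheduled times and adds
#' the method-specific systematic offset (TcB reads `tcb_offset` µmol/L above
#' the serum-equivalent scale by default) plus additive Gaussian noise with
#' the method's residual SD; values are truncated at zero.
#'
#' @param patient one row of [sample_covariates()] output.
#' @param schedule data frame with `pna` and `method` columns, sorted by
#'   `pna`.
#' @param pop a [population_model()].
#' @param config a [cohort_config()] (error overrides honoured).
#' @return A [bili_measurements()] set.
#' @export
simulate_measurements <- function(patient, schedule, pop,
                                  config = cohort_config()) {
  if (nrow(schedule) == 0L) return(bili_measurements())
  if (is.unsorted(schedule$pna)) stop("schedule times must be sorted")
  offset <- config$tcb_offset %||% pop$tcb_offset
  s_tsb <- config$sigma_tsb %||% pop$sigma_tsb
  s_tcb <- config$sigma_tcb %||% pop$sigma_tcb
  cov <- covariates(patient$ga_weeks, patient$birth_weight_g, patient$sex,
                    patient$delivery_mode, patient$hemolytic)
  truth <- trajectory(pop, cov, c(patient$eta1, patient$eta2), schedule$pna)
  is_tcb <- schedule$method == "TcB"
  sd <- ifelse(is_tcb, s_tcb, s_tsb)
  val <- truth + ifelse(is_tcb, offset, 0) + rnorm(length(truth), 0, sd)
  bili_measurements(schedule$pna, pmax(val, 0), schedule$method)
}

#' Generate a full synthetic cohort
#'
#' Composes [sample_covariates()], [sample_schedule()] and
#' [simulate_measurements()]: per-patient seeds are derived from the global
#' `config$seed`, so individual patients are independent of cohort size and
#' of each other. Optionally writes `patients.csv` and `measurements.csv`.
#'
#' @param config a [cohort_config()].
#' @param pop a [population_model()].
#' @param dir optional output directory for the two CSV files.
#' @return A list of class `bili_cohort` with `patients` and `measurements`
#'   data frames (`measurements` columns: `patient_id`, `pna_h`,
#'   `value_umol_l`, `method`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 1))
#' head(coh$measurements)
generate_cohort <- function(config = cohort_config(),
                            pop = population_model(), dir = NULL) {
  patients <- sample_covariates(config, pop)
  meas_list <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    withr_seed(child_seed(config$seed, 1000000 + i), {
      sched <- sample_schedule(config)
      m <- simulate_measurements(patients[i, ], sched, pop, config)
      meas_list[[i]] <- data.frame(patient_id = patients$patient_id[i],
                                   pna_h = m$pna, value_umol_l = m$value,
                                   method = m$method,
                                   stringsAsFactors = FALSE)
    })
  }
  measurements <- if (length(meas_list)) do.call(rbind, meas_list) else
    data.frame(patient_id = character(0), pna_h = numeric(0),
               value_umol_l = numeric(0), method = character(0),
               stringsAsFactors = FALSE)
  rownames(measurements) <- NULL
  out <- structure(list(patients = patients, measurements = measurements,
                        config = config),
                   class = "bili_cohort")
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write / read a cohort as CSV
#'
#' `patients.csv`: patient_id, ga_weeks, birth_weight_g, sex, delivery_mode,
#' hemolytic. `measurements.csv`: patient_id, pna_h, value_umol_l, method.
#' The hidden simulation-truth random effects are not written.
#'
#' @param cohort a `bili_cohort`.
#' @param dir directory.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `bili_cohort` (without simulation truth).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- cohort$patients
  pat$eta1 <- NULL
  pat$eta2 <- NULL
  write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(cohort$measurements, file.path(dir, "measurements.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  structure(list(
    patients = read.csv(file.path(dir, "patients.csv"),
                        stringsAsFactors = FALSE),
    measurements = read.csv(file.path(dir, "measurements.csv"),
                            stringsAsFactors = FALSE)),
    class = "bili_cohort")
}
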