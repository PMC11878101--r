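#' Two-stage calibration of the population model
#'
#' A deliberately simple calibration stand-in for full nonlinear mixed-effects
#' estimation (SAEM/FOCE are out of scope). Stage 1 fits each individual's
#' `k_in0` and `t50` by weighted least squares on the log scale, holding the
#' remaining structural constants at their values in `init`. Stage 2 divides
#' out each individual's covariate multipliers, sets the population fixed
#' effects to the geometric mean of the resulting individual parameters, the
#' random-effect covariance `omega` to the sample covariance of the log
#' deviations, and the residual SDs to the pooled stage-1 residual SD per
#' measurement method.
#'
#' Requires at least 20 individuals with at least 4 measurements each; with
#' fewer observations per subject the individual fits are not identifiable.
#'
#' @param cohort a cohort as returned by [generate_cohort()], or any list with
#'   `patients` (data frame: `patient_id`, `ga_weeks`, `birth_weight_g`,
#'   `sex`, `delivery_mode`, `hemolytic`) and `measurements` (data frame:
#'   `patient_id`, `pna_h`, `value_umol_l`, `method`).
#' @param init a [population_model()] providing the non-estimated structural
#'   constants and starting values.
#' @return A [population_model()] with calibrated `k_in0`, `t50`, `omega`,
#'   `sigma_tsb` and `sigma_tcb`.
#' @export
fit_population_two_stage <- function(cohort, init = population_model()) {
  pat <- cohort$patients
  mea <- cohort$measurements
  if (is.null(pat) || nrow(pat) < 20)
    stop("two-stage calibration needs at least 20 patients")
  counts <- table(mea$patient_id)
  if (!all(pat$patient_id %in% names(counts)) || any(counts[pat$patient_id] < 4))
    stop("every patient needs at least 4 measurements")

  log_kin <- numeric(nrow(pat))
  log_t50 <- numeric(nrow(pat))
  resid_tsb <- numeric(0)
  resid_tcb <- numeric(0)
  for (i in seq_len(nrow(pat))) {
    row <- pat[i, ]
    cov <- covariates(row$ga_weeks, row$birth_weight_g, row$sex,
                      row$delivery_mode, row$hemolytic)
    mi <- mea[mea$patient_id == row$patient_id, , drop = FALSE]
    m <- bili_measurements(mi$pna_h, mi$value_umol_l, mi$method)
    w <- 1 / sigma_for(init, m$method)^2
    # stage 1: unpenalized WLS in eta-space, i.e. log deviations of the
    # individual's k_in0 and t50 from their covariate-adjusted typicals
    obj <- function(eta) {
      b <- trajectory(init, cov, eta, m$pna)
      sum(w * (m$value - b)^2)
    }
    fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 2000))
    p <- individual_parameters(init, cov, fit$par)
    f_prod <- (if (cov$delivery_mode == "cesarean") init$coef$f_cesarean else 1) *
      (if (cov$hemolytic) init$coef$f_hemolytic else 1)
    ga_mult <- (cov$gestational_age / init$coef$ga_ref)^init$coef$beta_ga
    log_kin[i] <- log(p$k_in0 / f_prod)
    log_t50[i] <- log(p$t50 / ga_mult)
    r <- m$value - trajectory(init, cov, fit$par, m$pna)
    resid_tsb <- c(resid_tsb, r[m$method == "TSB"])
    resid_tcb <- c(resid_tcb, r[m$method == "TcB"])
  }

  dev <- cbind(log_kin - mean(log_kin), log_t50 - mean(log_t50))
  omega_hat <- crossprod(dev) / (nrow(dev) - 1)
  pooled_sd <- function(r, fallback) {
    if (length(r) >= 2) sqrt(mean(r^2)) else fallback
  }
  s_tsb <- pooled_sd(resid_tsb, init$sigma_tsb)
  s_tcb <- max(pooled_sd(resid_tcb, init$sigma_tcb), s_tsb)
  population_model(
    k_in0 = exp(mean(log_kin)), lambda_prod = init$fixed$lambda_prod,
    k_out_max = init$fixed$k_out_max, t50 = exp(mean(log_t50)),
    gamma = init$fixed$gamma, B0 = init$fixed$B0,
    beta_ga = init$coef$beta_ga, beta_wt = init$coef$beta_wt,
    f_cesarean = init$coef$f_cesarean, f_hemolytic = init$coef$f_hemolytic,
    ga_ref = init$coef$ga_ref, wt_ref = init$coef$wt_ref,
    omega = omega_hat, sigma_tsb = s_tsb, sigma_tcb = s_tcb,
    tcb_offset = init$tcb_offset)
}
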