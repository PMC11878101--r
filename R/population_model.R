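#' Population model for neonatal bilirubin kinetics
#'
#' Constructs the population (mixed-effects) parameterization of the bilirubin
#' turnover model
#' \deqn{dB/dt = k_{in}(t) - k_{out}(t)\,B,}
#' with production \eqn{k_{in}(t) = k_{in,0} e^{-\lambda_{prod} t}} declining
#' from birth and elimination \eqn{k_{out}(t) = k_{out,max}\, t^\gamma /
#' (t_{50}^\gamma + t^\gamma)} maturing over postnatal age (hours).
#'
#' The default fixed effects are calibration constants chosen so that the
#' typical trajectory of a reference term neonate rises from about 35 µmol/L
#' at birth to a single peak of roughly 230–250 µmol/L between 2 and 5 days of
#' postnatal age; they are not estimates from any clinical dataset and every
#' one of them is configurable.
#'
#' Random effects \eqn{\eta} act multiplicatively (log-normally) on
#' \code{k_in0} and \code{t50}, with diagonal covariance \code{omega} by
#' default. Residual error is additive Gaussian with a method-specific SD:
#' transcutaneous (TcB) readings are noisier than serum (TSB) readings.
#'
#' @param k_in0 production rate at birth, µmol/L per hour.
#' @param lambda_prod exponential decay rate of production, per hour.
#' @param k_out_max asymptotic (mature) elimination rate constant, per hour.
#' @param t50 postnatal age at half-maximal elimination maturation, hours.
#' @param gamma Hill coefficient of the elimination maturation curve.
#' @param B0 bilirubin concentration at birth, µmol/L.
#' @param beta_ga exponent of (GA / ga_ref) on \code{t50}; negative values
#'   make elimination mature more slowly in preterm neonates.
#' @param beta_wt allometric exponent of (weight / wt_ref) on \code{k_out_max}.
#' @param f_cesarean multiplicative factor on \code{k_in0} for cesarean birth.
#' @param f_hemolytic multiplicative factor on \code{k_in0} for hemolytic
#'   disease; must exceed 1 (hemolysis increases bilirubin production).
#' @param ga_ref,wt_ref reference gestational age (weeks) and birth weight (g)
#'   at which covariate multipliers equal 1.
#' @param omega 2x2 symmetric positive-definite covariance of the random
#'   effects on \code{log(k_in0)} and \code{log(t50)}.
#' @param sigma_tsb,sigma_tcb additive residual SDs (µmol/L) for TSB and TcB
#'   measurements; \code{sigma_tcb} must be >= \code{sigma_tsb}.
#' @param tcb_offset mean systematic offset of TcB above the TSB-equivalent
#'   scale, µmol/L.
#'
#' @return An object of class \code{bili_population_model}.
#' @export
#' @examples
#' pop <- population_model()
#' cov <- covariates()
#' individual_parameters(pop, cov, c(0, 0))
population_model <- function(k_in0 = 3.0,
                             lambda_prod = 0.003,
                             k_out_max = 0.05,
                             t50 = 120,
                             gamma = 5,
                             B0 = 35,
                             beta_ga = -3,
                             beta_wt = -0.25,
                             f_cesarean = 0.95,
                             f_hemolytic = 1.35,
                             ga_ref = 38.7,
                             wt_ref = 3500,
                             omega = diag(c(0.04, 0.04)),
                             sigma_tsb = 13.6,
                             sigma_tcb = 25.5,
                             tcb_offset = 14.3) {
  fixed <- c(k_in0 = k_in0, lambda_prod = lambda_prod, k_out_max = k_out_max,
             t50 = t50, gamma = gamma, B0 = B0)
  if (any(!is.finite(fixed)) || any(fixed <= 0))
    stop("all fixed effects must be finite and strictly positive")
  omega <- as.matrix(omega)
  if (nrow(omega) != 2L || ncol(omega) != 2L ||
      max(abs(omega - t(omega))) > 1e-10)
    stop("omega must be a symmetric 2x2 matrix")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("omega must be positive semi-definite")
  if (!is.finite(sigma_tsb) || sigma_tsb <= 0 ||
      !is.finite(sigma_tcb) || sigma_tcb <= 0)
    stop("residual SDs must be finite and positive")
  if (sigma_tcb < sigma_tsb)
    stop("sigma_tcb must be >= sigma_tsb (TcB is the noisier method)")
  if (f_hemolytic <= 1)
    stop("f_hemolytic must exceed 1: hemolysis increases production")
  structure(
    list(fixed = as.list(fixed),
         coef = list(beta_ga = beta_ga, beta_wt = beta_wt,
                     f_cesarean = f_cesarean, f_hemolytic = f_hemolytic,
                     ga_ref = ga_ref, wt_ref = wt_ref),
         omega = omega,
         sigma_tsb = sigma_tsb,
         sigma_tcb = sigma_tcb,
         tcb_offset = tcb_offset),
    class = "bili_population_model")
}

#' @export
print.bili_population_model <- function(x, ...) {
  cat("Neonatal bilirubin population model (turnover + maturation)\n")
  cat("  fixed effects:",
      paste(names(x$fixed), signif(unlist(x$fixed), 4), sep = "=",
            collapse = ", "), "\n")
  cat("  random effects on log(k_in0), log(t50); omega diag:",
      paste(signif(diag(x$omega), 4), collapse = ", "), "\n")
  cat(sprintf("  residual SD: TSB %.1f, TcB %.1f umol/L; TcB offset %.1f\n",
              x$sigma_tsb, x$sigma_tcb, x$tcb_offset))
  invisible(x)
}

#' Neonate covariate record
#'
#' Covariates entering the individual parameterization. Inclusion rules of the
#' validation design are enforced: gestational age at least 34 completed weeks
#' and birth weight at least 1500 g.
#'
#' @param gestational_age gestational age at birth, weeks (decimal).
#' @param birth_weight birth weight, grams.
#' @param sex \code{"female"} or \code{"male"}.
#' @param delivery_mode \code{"vaginal"} or \code{"cesarean"}.
#' @param hemolytic logical; hemolytic disease (incl. blood group
#'   incompatibility).
#' @return An object of class \code{bili_covariates}.
#' @export
covariates <- function(gestational_age = 38.7, birth_weight = 3500,
                       sex = c("female", "male"),
                       delivery_mode = c("vaginal", "cesarean"),
                       hemolytic = FALSE) {
  sex <- match.arg(sex)
  delivery_mode <- match.arg(delivery_mode)
  if (!is.finite(gestational_age) || gestational_age < 34)
    stop("gestational_age must be >= 34 weeks (inclusion rule)")
  if (!is.finite(birth_weight) || birth_weight < 1500)
    stop("birth_weight must be >= 1500 g (exclusion rule)")
  structure(list(gestational_age = gestational_age,
                 birth_weight = birth_weight, sex = sex,
                 delivery_mode = delivery_mode,
                 hemolytic = isTRUE(hemolytic)),
            class = "bili_covariates")
}

#' Map population parameters, covariates and random effects to an individual
#'
#' Each structural parameter is its fixed effect times a covariate multiplier
#' times \code{exp(eta)} for the parameters carrying a random effect:
#' \itemize{
#'   \item \code{k_in0}: delivery-mode and hemolysis factors, \code{exp(eta[1])};
#'   \item \code{t50}: \code{(GA/ga_ref)^beta_ga}, \code{exp(eta[2])};
#'   \item \code{k_out_max}: \code{(weight/wt_ref)^beta_wt}.
#' }
#' Sex is recorded but carries no effect by default (the algorithm's stated
#' inputs are GA, birth weight and delivery mode).
#'
#' @param pop a [population_model()].
#' @param cov a [covariates()] record.
#' @param eta numeric length-2 random-effect vector (log-scale perturbations
#'   of \code{k_in0} and \code{t50}).
#' @return Named list of strictly positive structural parameters
#'   (\code{k_in0}, \code{lambda_prod}, \code{k_out_max}, \code{t50},
#'   \code{gamma}, \code{B0}).
#' @export
individual_parameters <- function(pop, cov, eta = c(0, 0)) {
  stopifnot(inherits(pop, "bili_population_model"),
            inherits(cov, "bili_covariates"))
  eta <- as.numeric(eta)
  if (length(eta) != nrow(pop$omega) || any(!is.finite(eta)))
    stop("eta must be a finite vector matching dim(omega)")
  fx <- pop$fixed
  cf <- pop$coef
  f_prod <- (if (cov$delivery_mode == "cesarean") cf$f_cesarean else 1) *
    (if (cov$hemolytic) cf$f_hemolytic else 1)
  list(
    k_in0 = fx$k_in0 * f_prod * exp(eta[1]),
    lambda_prod = fx$lambda_prod,
    k_out_max = fx$k_out_max * (cov$birth_weight / cf$wt_ref)^cf$beta_wt,
    t50 = fx$t50 * (cov$gestational_age / cf$ga_ref)^cf$beta_ga * exp(eta[2]),
    gamma = fx$gamma,
    B0 = fx$B0)
}

#' Serialize / deserialize a population model as flat JSON
#'
#' The document is a flat key-value map (omega stored by its three free
#' entries), round-trip safe to full double precision.
#'
#' @param pop a [population_model()].
#' @param path file path to write to / read from.
#' @return `read_population_model` returns a [population_model()];
#'   `write_population_model` returns `path` invisibly.
#' @export
write_population_model <- function(pop, path) {
  stopifnot(inherits(pop, "bili_population_model"))
  doc <- c(pop$fixed, pop$coef,
           list(omega_11 = pop$omega[1, 1], omega_22 = pop$omega[2, 2],
                omega_12 = pop$omega[1, 2],
                sigma_tsb = pop$sigma_tsb, sigma_tcb = pop$sigma_tcb,
                tcb_offset = pop$tcb_offset))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population_model
#' @export
read_population_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_model(
    k_in0 = doc$k_in0, lambda_prod = doc$lambda_prod,
    k_out_max = doc$k_out_max, t50 = doc$t50, gamma = doc$gamma, B0 = doc$B0,
    beta_ga = doc$beta_ga, beta_wt = doc$beta_wt,
    f_cesarean = doc$f_cesarean, f_hemolytic = doc$f_hemolytic,
    ga_ref = doc$ga_ref, wt_ref = doc$wt_ref,
    omega = matrix(c(doc$omega_11, doc$omega_12, doc$omega_12, doc$omega_22),
                   2, 2),
    sigma_tsb = doc$sigma_tsb, sigma_tcb = doc$sigma_tcb,
    tcb_offset = doc$tcb_offset)
}
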