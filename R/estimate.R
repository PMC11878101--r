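#' Empirical Bayes (MAP) estimation of individual random effects
#'
#' Estimates the individual random-effect vector \eqn{\eta} from up to three
#' bilirubin measurements by minimizing the penalized weighted residual sum
#' of squares
#' \deqn{\sum_j \frac{(B_{obs,j} - B(t_j;\eta))^2}{\sigma^2_{method(j)}}
#'       + \eta^\top \Omega^{-1} \eta,}
#' the mode of the posterior under the log-normal population prior. With no
#' measurements the prior mode \eqn{\eta = 0} is returned with objective 0.
#'
#' Optimization is a Nelder-Mead local search started at \eqn{\eta = 0}
#' (relative tolerance 1e-8); if the optimizer ends above the prior-mode
#' objective the prior mode is returned instead, so the estimate never
#' worsens the objective.
#'
#' @param pop a [population_model()].
#' @param cov a [covariates()] record.
#' @param measurements a [bili_measurements()] set (0-3 rows typical; more
#'   are accepted).
#' @return A list of class `bili_eta_estimate` with elements `eta`,
#'   `objective_value` and `n_measurements_used`.
#' @export
estimate_eta_map <- function(pop, cov, measurements) {
  stopifnot(inherits(pop, "bili_population_model"))
  m <- as_measurements(measurements)
  k <- nrow(pop$omega)
  if (nrow(m) == 0L) {
    return(structure(list(eta = numeric(k), objective_value = 0,
                          n_measurements_used = 0L),
                     class = "bili_eta_estimate"))
  }
  if (any(!is.finite(m$value)))
    stop("measurement values must be finite")
  sig2 <- sigma_for(pop, m$method)^2
  omega_inv <- solve(pop$omega)
  objective <- function(eta) {
    b <- trajectory(pop, cov, eta, m$pna)
    sum((m$value - b)^2 / sig2) + drop(crossprod(eta, omega_inv %*% eta))
  }
  obj0 <- objective(numeric(k))
  fit <- optim(numeric(k), objective, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 2000))
  if (fit$convergence != 0)
    stop(sprintf("MAP optimizer did not converge (code %d): %s",
                 fit$convergence, paste(fit$message, collapse = " ")))
  if (fit$value <= obj0) {
    eta <- fit$par; val <- fit$value
  } else {
    eta <- numeric(k); val <- obj0
  }
  structure(list(eta = eta, objective_value = val,
                 n_measurements_used = nrow(m)),
            class = "bili_eta_estimate")
}

#' Prediction horizon permitted by the measurement methods
#'
#' 60 h when every input is a serum (TSB) measurement, otherwise 48 h.
#'
#' @param methods character vector of input methods.
#' @return Horizon in hours.
#' @export
default_horizon_limit <- function(methods) {
  if (length(methods) && all(methods == "TSB")) 60 else 48
}

#' Predict an individual's bilirubin concentration at a target time
#'
#' Runs MAP estimation on the input measurements and evaluates the individual
#' trajectory at `t_target`. The target must lie strictly after the last
#' input and within the permitted horizon: 60 h beyond the last measurement
#' when all inputs are TSB, 48 h when any input is transcutaneous. With no
#' measurements the population-typical trajectory is used.
#'
#' @inheritParams estimate_eta_map
#' @param t_target postnatal age to predict at, hours.
#' @param horizon_limit maximal allowed `t_target - t_last`, hours; default
#'   derived from the input methods via [default_horizon_limit()].
#' @return Predicted concentration (µmol/L), nonnegative.
#' @export
#' @examples
#' pop <- population_model()
#' cov <- covariates()
#' m <- bili_measurements(c(30, 50), c(150, 190), "TSB")
#' predict_bilirubin(pop, cov, m, t_target = 90)
predict_bilirubin <- function(pop, cov, measurements, t_target,
                              horizon_limit = NULL) {
  m <- as_measurements(measurements)
  if (is.null(horizon_limit)) horizon_limit <- default_horizon_limit(m$method)
  t_last <- if (nrow(m)) max(m$pna) else 0
  if (!is.finite(t_target) || t_target <= t_last)
    stop("t_target must lie strictly after the last input measurement")
  if (t_target - t_last > horizon_limit)
    stop(sprintf(
      "prediction horizon exceeded: t_target - t_last = %.1f h > limit %.1f h",
      t_target - t_last, horizon_limit))
  est <- estimate_eta_map(pop, cov, m)
  as.numeric(trajectory(pop, cov, est$eta, t_target))
}
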