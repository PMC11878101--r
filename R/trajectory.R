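#' Individual bilirubin trajectory
#'
#' Solves the turnover ODE \eqn{dB/dt = k_{in}(t) - k_{out}(t) B} for one
#' individual and returns concentrations at the requested postnatal ages.
#' Integration uses a fixed-step fourth-order Runge-Kutta scheme on an
#' internal grid (default step 0.125 h) with cubic Hermite dense output, so
#' the value returned at a given time does not depend on which other times
#' are requested.
#'
#' @param pop a [population_model()].
#' @param cov a [covariates()] record.
#' @param eta random-effect vector (default prior mode, zeros).
#' @param times numeric vector of postnatal ages in hours, nonnegative and
#'   sorted increasingly.
#' @param step internal integrator step, hours.
#' @return Numeric vector of bilirubin concentrations (µmol/L), nonnegative,
#'   same length as `times`.
#' @export
#' @examples
#' pop <- population_model()
#' trajectory(pop, covariates(), times = c(24, 48, 96))
trajectory <- function(pop, cov, eta = c(0, 0), times, step = 0.125) {
  if (length(times) == 0L) return(numeric(0))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  p <- individual_parameters(pop, cov, eta)
  .traj_rk4(as.numeric(times), p$B0, p$k_in0, p$lambda_prod,
            p$k_out_max, p$t50, p$gamma, step)
}
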