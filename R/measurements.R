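#' Construct a set of bilirubin measurements
#'
#' A measurement set is a data frame with columns `pna` (postnatal age,
#' hours), `value` (µmol/L) and `method` (`"TSB"` or `"TcB"`), sorted by
#' `pna`. This is the exchange format between the cohort generator, the
#' scenario builder and the estimator.
#'
#' @param pna numeric postnatal ages, hours, nonnegative.
#' @param value numeric concentrations, µmol/L, finite and nonnegative.
#' @param method character, `"TSB"` or `"TcB"` (recycled if length 1).
#' @return A data frame of class `bili_measurements`.
#' @export
#' @examples
#' bili_measurements(c(30, 50), c(140, 180), "TSB")
bili_measurements <- function(pna = numeric(0), value = numeric(0),
                              method = character(0)) {
  if (length(method) == 1L) method <- rep(method, length(pna))
  if (length(pna) != length(value) || length(pna) != length(method))
    stop("pna, value and method must have equal length")
  if (length(pna)) {
    if (any(!is.finite(pna)) || any(pna < 0))
      stop("pna must be finite and nonnegative")
    if (any(!is.finite(value)) || any(value < 0))
      stop("values must be finite and nonnegative")
    if (!all(method %in% c("TSB", "TcB")))
      stop("method must be 'TSB' or 'TcB'")
  }
  out <- data.frame(pna = as.numeric(pna), value = as.numeric(value),
                    method = as.character(method),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bili_measurements", "data.frame")
  out
}

as_measurements <- function(df) {
  bili_measurements(df$pna, df$value, df$method)
}

sigma_for <- function(pop, method) {
  ifelse(method == "TcB", pop$sigma_tcb, pop$sigma_tsb)
}
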