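#' Prediction-error metrics
#'
#' Signed prediction error `PE = B_pred - B_obs` (µmol/L; negative values are
#' under-predictions, the clinically risky direction), its absolute value
#' `aPE`, and the relative error `rPE = 100 * |B_pred - B_obs| / B_obs`
#' (percent of the observed value).
#'
#' @param b_pred,b_obs predicted and observed bilirubin, µmol/L.
#' @return Numeric vector (vectorized over inputs).
#' @export
#' @examples
#' prediction_error(150, 244)   # -94, an under-prediction
#' relative_prediction_error(110, 100)  # 10
prediction_error <- function(b_pred, b_obs) {
  if (any(!is.finite(b_pred)) || any(!is.finite(b_obs)))
    stop("b_pred and b_obs must be finite")
  b_pred - b_obs
}

#' @rdname prediction_error
#' @export
absolute_prediction_error <- function(b_pred, b_obs) {
  abs(prediction_error(b_pred, b_obs))
}

#' @rdname prediction_error
#' @export
relative_prediction_error <- function(b_pred, b_obs) {
  if (any(b_obs <= 0))
    stop("rPE is undefined for nonpositive observed values")
  100 * abs(prediction_error(b_pred, b_obs)) / b_obs
}

#' Bland-Altman margin of error of the prediction errors
#'
#' Limits of agreement are `mean(PE) +/- 1.96 * SD(PE)` with the sample
#' (n-1) standard deviation; the margin is the larger absolute limit. This is
#' the "margin of error of the 95% confidence interval" entering the clinical
#' acceptance and exactness criteria. Setting `se_of_mean = TRUE` gives the
#' narrower standard-error-of-the-mean variant instead.
#'
#' @param pe numeric vector of signed prediction errors (>= 2 values).
#' @param se_of_mean use `SD/sqrt(n)` in place of `SD`.
#' @return Margin, µmol/L.
#' @export
#' @examples
#' bland_altman_margin(c(-10, 10))  # 1.96 * sqrt(200)
bland_altman_margin <- function(pe, se_of_mean = FALSE) {
  if (length(pe) < 2) stop("need at least 2 prediction errors")
  s <- sd(pe)
  if (se_of_mean) s <- s / sqrt(length(pe))
  lims <- mean(pe) + c(-1.96, 1.96) * s
  max(abs(lims))
}

#' Default acceptance thresholds
#'
#' The 85 µmol/L bound is the gap between gestational-age-specific
#' phototherapy and exchange-transfusion thresholds; 70 µmol/L is the
#' stricter exactness margin.
#'
#' @param clinical_margin,exact_margin Bland-Altman margin bounds, µmol/L.
#' @param clinical_miss_fraction minimum fraction of aPE within
#'   `miss_threshold`.
#' @param miss_threshold aPE bound defining a clinically relevant
#'   mis-prediction, µmol/L.
#' @return List of class `bili_thresholds`.
#' @export
acceptance_thresholds <- function(clinical_margin = 85,
                                  clinical_miss_fraction = 0.95,
                                  exact_margin = 70,
                                  miss_threshold = 85) {
  if (exact_margin >= clinical_margin)
    stop("exact_margin must be below clinical_margin")
  structure(list(clinical_margin = clinical_margin,
                 clinical_miss_fraction = clinical_miss_fraction,
                 exact_margin = exact_margin,
                 miss_threshold = miss_threshold),
            class = "bili_thresholds")
}

#' Clinically relevant mis-prediction counts
#'
#' Counts of `PE < -threshold` (under-predictions) and `PE > +threshold`
#' (over-predictions) — strict inequalities, so a PE of exactly -85 falls in
#' neither tail — with percentages of n rounded half-away-from-zero to one
#' decimal.
#'
#' @param pe signed prediction errors (n >= 1).
#' @param thresholds an [acceptance_thresholds()].
#' @return List with `n_under`, `pct_under`, `n_over`, `pct_over`.
#' @export
misprediction_counts <- function(pe, thresholds = acceptance_thresholds()) {
  if (!length(pe)) stop("no prediction errors supplied")
  thr <- thresholds$miss_threshold
  n <- length(pe)
  n_under <- sum(pe < -thr)
  n_over <- sum(pe > thr)
  list(n_under = n_under, pct_under = round_half_away(100 * n_under / n, 1),
       n_over = n_over, pct_over = round_half_away(100 * n_over / n, 1))
}

#' Clinical-acceptance and exactness verdicts
#'
#' Clinical acceptance: (i) Bland-Altman margin within +/- 85 µmol/L and
#' (ii) at least 95% of absolute prediction errors not exceeding 85 µmol/L.
#' Exactness (stricter): (i) margin within +/- 70 µmol/L and (ii) no absolute
#' prediction error above 85 µmol/L. Both sub-conditions are reported; a
#' fraction sitting exactly on the 95% boundary is flagged.
#'
#' @param pe signed prediction errors (n >= 2).
#' @param thresholds an [acceptance_thresholds()].
#' @return List with `pass`, `margin`, `margin_ok`, and for the clinical
#'   criterion `frac_within`, `frac_ok`, `boundary` / for exactness
#'   `max_ape`, `miss_ok`.
#' @export
clinical_acceptance <- function(pe, thresholds = acceptance_thresholds()) {
  margin <- bland_altman_margin(pe)
  frac <- mean(abs(pe) <= thresholds$miss_threshold)
  margin_ok <- margin <= thresholds$clinical_margin
  frac_ok <- frac >= thresholds$clinical_miss_fraction
  list(pass = margin_ok && frac_ok, margin = margin, margin_ok = margin_ok,
       frac_within = frac, frac_ok = frac_ok,
       boundary = isTRUE(all.equal(frac, thresholds$clinical_miss_fraction)))
}

#' @rdname clinical_acceptance
#' @export
exactness <- function(pe, thresholds = acceptance_thresholds()) {
  margin <- bland_altman_margin(pe)
  max_ape <- max(abs(pe))
  margin_ok <- margin <= thresholds$exact_margin
  miss_ok <- max_ape <= thresholds$miss_threshold
  list(pass = margin_ok && miss_ok, margin = margin, margin_ok = margin_ok,
       max_ape = max_ape, miss_ok = miss_ok)
}

#' Harmonize TcB and TSB measurements onto the target's scale
#'
#' TcB readings sit on average `offset` µmol/L above the serum-equivalent
#' scale (default 14.3). Measurements whose method differs from the target's
#' are shifted onto the target's scale: TcB values are lowered by `offset`
#' when the target is TSB, TSB values raised by `offset` when the target is
#' TcB. Measurements already on the target scale are untouched, so the
#' operation is idempotent, and harmonizing back to the original scale
#' restores the original values.
#'
#' @param measurements a [bili_measurements()] set.
#' @param target_method `"TSB"` or `"TcB"`.
#' @param offset signed magnitude of the TcB-above-TSB offset, µmol/L.
#' @return A [bili_measurements()] set with adjusted values (methods are
#'   relabelled to `target_method` to record the harmonized scale).
#' @export
#' @examples
#' m <- bili_measurements(30, 150, "TcB")
#' harmonize(m, "TSB")$value  # 135.7
harmonize <- function(measurements, target_method, offset = 14.3) {
  if (!target_method %in% c("TSB", "TcB"))
    stop("unknown target method: ", target_method)
  m <- as_measurements(measurements)
  shift <- ifelse(m$method == target_method, 0,
                  ifelse(target_method == "TSB", -offset, +offset))
  bili_measurements(m$pna, pmax(m$value + shift, 0),
                    rep(target_method, nrow(m)))
}

#' Bilirubin rate of increase
#'
#' `(B_target - B_last) / (t_target - t_last)`, reported in mg/dl per hour
#' (inputs in µmol/L are divided by the molar conversion 17.1 µmol/L per
#' mg/dl). `B_target` may be the observed or the predicted target value.
#'
#' @param b_target,b_last bilirubin at target and at the last input, µmol/L.
#' @param t_target,t_last postnatal ages, hours (`t_target > t_last`).
#' @return Rate in mg/dl per hour (vectorized).
#' @export
#' @examples
#' increase_rate(184.2, 150, 58, 48)  # 0.2 mg/dl per hour
increase_rate <- function(b_target, b_last, t_target, t_last) {
  if (any(t_target <= t_last))
    stop("t_target must be strictly after t_last")
  ((b_target - b_last) / UMOL_PER_MGDL) / (t_target - t_last)
}

#' Summarize a set of prediction records
#'
#' Computes the full per-scenario validation summary: n, Bland-Altman margin,
#' median (IQR) of aPE and of rPE (linear-interpolation quantiles), strict
#' mis-prediction counts with one-decimal percentages, and the clinical
#' acceptance and exactness verdicts.
#'
#' @param records data frame with columns `b_pred` and `b_obs` (µmol/L);
#'   additional columns are ignored.
#' @param thresholds an [acceptance_thresholds()].
#' @return List of class `bili_validation_summary`.
#' @export
summarize_validation <- function(records,
                                 thresholds = acceptance_thresholds()) {
  if (nrow(records) < 2) stop("need at least 2 prediction records")
  pe <- prediction_error(records$b_pred, records$b_obs)
  ape <- abs(pe)
  rpe <- relative_prediction_error(records$b_pred, records$b_obs)
  q <- function(x) unname(quantile(x, c(0.5, 0.25, 0.75), type = 7))
  mc <- misprediction_counts(pe, thresholds)
  structure(list(
    n = nrow(records),
    margin_95ci = bland_altman_margin(pe),
    median_iqr_ape = setNames(q(ape), c("median", "q1", "q3")),
    median_iqr_rpe = setNames(q(rpe), c("median", "q1", "q3")),
    n_under = mc$n_under, pct_under = mc$pct_under,
    n_over = mc$n_over, pct_over = mc$pct_over,
    clinical_acceptance = clinical_acceptance(pe, thresholds),
    exactness = exactness(pe, thresholds)),
    class = "bili_validation_summary")
}

#' @export
print.bili_validation_summary <- function(x, ...) {
  cat(sprintf("n = %d | margin of error (95%% CI) = %.1f umol/L\n",
              x$n, x$margin_95ci))
  cat(sprintf("median (IQR) aPE = %.1f (%.1f, %.1f) umol/L\n",
              x$median_iqr_ape[1], x$median_iqr_ape[2], x$median_iqr_ape[3]))
  cat(sprintf("median (IQR) rPE = %.1f%% (%.1f, %.1f)\n",
              x$median_iqr_rpe[1], x$median_iqr_rpe[2], x$median_iqr_rpe[3]))
  cat(sprintf("under-predictions PE < -85: %d (%.1f%%); over +85: %d (%.1f%%)\n",
              x$n_under, x$pct_under, x$n_over, x$pct_over))
  cat(sprintf("clinical acceptance: %s | exactness: %s\n",
              if (x$clinical_acceptance$pass) "pass" else "fail",
              if (x$exactness$pass) "pass" else "fail"))
  invisible(x)
}
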