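# Accuracy, test-retest repeatability, agreement and QC statistics used to
# compare modelled flow values between sessions and PET/CT systems.

#' Flow-value error relative to the reference flow
#'
#' `100 x |flow - Qref| / Qref`, the absolute percent error of a modelled
#' flow value against the flow-meter-derived reference.
#'
#' @param flow Modelled flow value(s) (ml/min).
#' @param qref Reference flow (ml/min), > 0.
#' @return Percent error(s), nonnegative.
#' @export
flow_value_error <- function(flow, qref) {
  stop_if(any(qref <= 0), "qref must be positive")
  100 * abs(flow - qref) / qref
}

#' Test-retest repeatability error
#'
#' `100 x (retest - test) / test`; the absolute value is returned by
#' default, the signed variant reproduces printed difference columns.
#'
#' @param test,retest Paired measurements (test value nonzero).
#' @param signed Return the signed percent difference instead of its
#'   absolute value.
#' @return Percent difference(s).
#' @export
repeatability_error <- function(test, retest, signed = FALSE) {
  stop_if(any(test == 0), "test value must be nonzero")
  err <- 100 * (retest - test) / test
  if (signed) err else abs(err)
}

#' Mean and sample standard deviation of a set of errors
#'
#' @param values Numeric vector, non-empty.
#' @return List with `n`, `mean` and `sd` (sample SD, n-1 denominator;
#'   `NA` for a single value).
#' @export
summary_stats <- function(values) {
  stop_if(length(values) == 0L, "empty input")
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Count values strictly exceeding a threshold
#'
#' @param values Numeric vector.
#' @param threshold_percent Nonnegative threshold.
#' @export
count_exceeding <- function(values, threshold_percent) {
  stop_if(threshold_percent < 0, "threshold must be nonnegative")
  sum(values > threshold_percent)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` summarised as mean, sample SD and limits of
#' agreement `mean +/- 1.96 x SD`.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @return List with `n`, `mean_difference`, `sd_difference`, `loa_low`,
#'   `loa_high`.
#' @export
bland_altman <- function(values_a, values_b) {
  stop_if(length(values_a) != length(values_b), "inputs must have equal length")
  stop_if(length(values_a) < 2L, "need at least two pairs")
  d <- values_a - values_b
  m <- mean(d); s <- stats::sd(d)
  list(n = length(d), mean_difference = m, sd_difference = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Ordinary least-squares line and Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 2; `x` must not be
#'   constant.
#' @return List with `slope`, `intercept` and `r`.
#' @export
linear_fit <- function(x, y) {
  stop_if(length(x) != length(y), "inputs must have equal length")
  stop_if(length(x) < 2L, "need at least two points")
  stop_if(stats::sd(x) == 0, "x is constant; line is undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(x, y))
}

#' Flow-meter quality control
#'
#' Ideally all pumped water splits between the exchange cylinder and the
#' perforated tube, so `Qcyl + Qtube = Qpump`. The QC statistic is the
#' signed percent deviation `100 x (Qcyl + Qtube - Qpump) / Qpump`, passed
#' when its magnitude is within `limit_percent`.
#'
#' @param qcyl_measured,qtube_measured Flow-meter readings (ml/min).
#' @param qpump Set pump flow (ml/min), > 0.
#' @param limit_percent QC limit, default 15.
#' @return List with `observed_percent`, `limit_percent` and `passed`
#'   (vectorised over the readings).
#' @export
flowmeter_qc <- function(qcyl_measured, qtube_measured, qpump,
                         limit_percent = 15) {
  stop_if(any(qpump <= 0), "qpump must be positive")
  observed <- 100 * (qcyl_measured + qtube_measured - qpump) / qpump
  list(observed_percent = observed, limit_percent = limit_percent,
       passed = abs(observed) <= limit_percent)
}

#' Injected-activity quality control
#'
#' Percent deviation of the dispensed activity from the requested level
#' (500 MBq in the study protocol); the dispenser is specified to 15%.
#'
#' @param injected_MBq Dispensed activity (MBq).
#' @param requested_MBq Requested activity (MBq), > 0.
#' @param limit_percent QC limit, default 15.
#' @return List with `observed_percent` (absolute), `limit_percent`,
#'   `passed`.
#' @export
activity_qc <- function(injected_MBq, requested_MBq = 500, limit_percent = 15) {
  stop_if(any(requested_MBq <= 0), "requested activity must be positive")
  observed <- 100 * abs(injected_MBq - requested_MBq) / requested_MBq
  list(observed_percent = observed, limit_percent = limit_percent,
       passed = observed <= limit_percent)
}
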