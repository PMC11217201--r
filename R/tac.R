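#' Continuous activity-concentration curve
#'
#' The high-resolution precursor of a frame-sampled time-activity curve:
#' activity concentration (kBq/ml) on a strictly increasing time grid (s).
#' Values are interpreted piecewise linearly between grid points.
#'
#' @param time Numeric, strictly increasing time grid (s).
#' @param values Numeric activity concentration (kBq/ml), finite.
#' @return An object of class `continuous_curve`.
#' @export
continuous_curve <- function(time, values) {
  stop_if(length(time) < 1L, "a curve needs at least one time point")
  stop_if(length(time) != length(values), "time and values lengths differ")
  stop_if(any(diff(time) <= 0), "time grid must be strictly increasing")
  stop_if(any(!is.finite(values)), "curve values must be finite")
  structure(list(time = as.numeric(time), values = as.numeric(values)),
            class = "continuous_curve")
}

#' @export
print.continuous_curve <- function(x, ...) {
  cat(sprintf("<continuous_curve> %d points over [%.6g, %.6g] s, peak %.4g kBq/ml\n",
              length(x$time), x$time[1L], x$time[length(x$time)], max(x$values)))
  invisible(x)
}

#' Frame-sampled time-activity curve
#'
#' One activity-concentration value (kBq/ml) per frame of a
#' [frame_schedule()], plus the decay-correction state. `reference_time` is
#' the time point activities are decay-corrected to (default 0 = injection).
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric, one finite value per frame.
#' @param decay_corrected Logical flag; `TRUE` if the values have been
#'   referenced to `reference_time` with [decay_correct()].
#' @param reference_time Decay-correction reference time (s).
#' @return An object of class `sampled_tac`.
#' @export
sampled_tac <- function(schedule, values, decay_corrected = FALSE,
                        reference_time = 0) {
  stop_if(!inherits(schedule, "frame_schedule"), "schedule must be a frame_schedule")
  stop_if(length(values) != n_frames(schedule),
          "need exactly one value per frame (", n_frames(schedule), ")")
  stop_if(any(!is.finite(values)), "TAC values must be finite")
  structure(list(schedule = schedule, values = as.numeric(values),
                 decay_corrected = isTRUE(decay_corrected),
                 reference_time = as.numeric(reference_time)),
            class = "sampled_tac")
}

#' @export
print.sampled_tac <- function(x, ...) {
  cat(sprintf("<sampled_tac> %d frames over %.6g s, peak %.4g kBq/ml, %s\n",
              n_frames(x$schedule), total_duration(x$schedule), max(x$values),
              if (x$decay_corrected) "decay-corrected" else "physical (not decay-corrected)"))
  invisible(x)
}

#' @export
as.data.frame.sampled_tac <- function(x, ...) {
  data.frame(frame_start_s = x$schedule$frame_starts,
             frame_duration_s = x$schedule$frame_durations,
             value_kBq_ml = x$values)
}

#' Sample a continuous curve onto a frame schedule
#'
#' Each frame value is the time-average of the (piecewise-linear) curve over
#' the half-open frame interval, mimicking how a PET scanner accumulates
#' counts within a frame.
#'
#' @param curve A [continuous_curve()] covering the schedule span.
#' @param schedule A [frame_schedule()].
#' @param decay_corrected Decay-correction state to record on the result
#'   (the sampling itself neither applies nor removes decay).
#' @return A [sampled_tac()].
#' @export
sample_frames <- function(curve, schedule, decay_corrected = FALSE) {
  stop_if(!inherits(curve, "continuous_curve"), "curve must be a continuous_curve")
  span_ok <- curve$time[1L] <= schedule$frame_starts[1L] + 1e-9 &&
    curve$time[length(curve$time)] >= max(frame_ends(schedule)) - 1e-9
  stop_if(!span_ok, "schedule extends past the curve support")
  sampled_tac(schedule, frame_average(curve$time, curve$values, schedule),
              decay_corrected = decay_corrected)
}

#' Area under the curve
#'
#' Trapezoidal time-integral for a [continuous_curve()]; sum of
#' `value x duration` for a [sampled_tac()]. Units: value-units x seconds.
#'
#' @param x A curve or sampled TAC.
#' @param ... Unused.
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.continuous_curve <- function(x, ...) {
  stop_if(length(x$time) < 2L, "a single point has no duration to integrate over")
  pwl_integral(x$time, x$values, x$time[1L], x$time[length(x$time)])
}

#' @rdname auc
#' @export
auc.sampled_tac <- function(x, ...) sum(x$values * x$schedule$frame_durations)
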