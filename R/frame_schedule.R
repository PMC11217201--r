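#' Dynamic acquisition frame schedule
#'
#' A frame schedule is the timing grid of a dynamic PET acquisition: frame
#' start times and durations in seconds, contiguous and non-overlapping,
#' starting at the injection time (t = 0 by convention).
#'
#' @param frame_starts Numeric vector of frame start times (s).
#' @param frame_durations Numeric vector of frame durations (s), all > 0.
#' @return An object of class `frame_schedule` with fields `frame_starts`
#'   and `frame_durations`.
#' @seealso [build_frame_schedule()], [default_frame_schedule()]
#' @export
frame_schedule <- function(frame_starts, frame_durations) {
  stop_if(length(frame_starts) == 0L, "schedule must contain at least one frame")
  stop_if(length(frame_starts) != length(frame_durations),
          "frame_starts and frame_durations must have equal length")
  stop_if(any(!is.finite(frame_starts)) || any(!is.finite(frame_durations)),
          "frame times must be finite")
  stop_if(any(frame_durations <= 0), "frame durations must be positive")
  n <- length(frame_starts)
  if (n > 1L) {
    gaps <- frame_starts[-1L] - (frame_starts[-n] + frame_durations[-n])
    stop_if(any(abs(gaps) > 1e-9),
            "frames must be contiguous and non-overlapping")
  }
  structure(list(frame_starts = as.numeric(frame_starts),
                 frame_durations = as.numeric(frame_durations)),
            class = "frame_schedule")
}

#' Build a frame schedule from (count, duration) blocks
#'
#' @param spec A list of length-2 numeric vectors `c(count, duration_s)`,
#'   e.g. `list(c(14, 5), c(3, 10), c(3, 20), c(4, 30))` for the clinical
#'   radiowater perfusion protocol (24 frames, 280 s).
#' @param start Start time of the first frame (s), default 0.
#' @return A [frame_schedule()].
#' @examples
#' build_frame_schedule(list(c(14, 5), c(3, 10), c(3, 20), c(4, 30)))
#' @export
build_frame_schedule <- function(spec, start = 0) {
  stop_if(length(spec) == 0L, "empty frame specification")
  durations <- unlist(lapply(spec, function(block) {
    stop_if(length(block) != 2L, "each block must be c(count, duration)")
    count <- block[1L]
    stop_if(count < 1 || count != round(count), "frame count must be a positive integer")
    stop_if(block[2L] <= 0, "frame duration must be positive")
    rep(block[2L], count)
  }))
  starts <- start + cumsum(c(0, durations[-length(durations)]))
  frame_schedule(starts, durations)
}

#' The clinical 24-frame radiowater schedule
#'
#' 14 x 5 s, 3 x 10 s, 3 x 20 s, 4 x 30 s; 24 frames covering 280 s.
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  build_frame_schedule(list(c(14, 5), c(3, 10), c(3, 20), c(4, 30)))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.6g s total (%.6g - %.6g s)\n",
              n_frames(x), total_duration(x),
              x$frame_starts[1L], frame_ends(x)[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A [frame_schedule()].
#' @export
n_frames <- function(schedule) length(schedule$frame_starts)

#' Frame end times (s)
#' @param schedule A [frame_schedule()].
#' @export
frame_ends <- function(schedule) schedule$frame_starts + schedule$frame_durations

#' Frame midpoint times (s)
#' @param schedule A [frame_schedule()].
#' @export
frame_mids <- function(schedule) schedule$frame_starts + schedule$frame_durations / 2

#' Total scheduled duration (s)
#' @param schedule A [frame_schedule()].
#' @export
total_duration <- function(schedule) sum(schedule$frame_durations)

schedules_equal <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    all(abs(a$frame_starts - b$frame_starts) <= tol) &&
    all(abs(a$frame_durations - b$frame_durations) <= tol)
}
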