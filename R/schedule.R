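#' Acquisition frame schedule
#'
#' A `frame_schedule` describes how dynamic PET list-mode data were
#' histogrammed into time frames. Frames must be contiguous, non-overlapping
#' and of strictly positive duration; all times are minutes post injection.
#' Frame mid-times (`mid`) are derived and used as the nominal sampling times
#' of frame-binned time--activity curves.
#'
#' @param start numeric vector of frame start times (min post injection).
#' @param duration numeric vector of frame durations (min), same length.
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration`, `mid` (= start + duration/2) and `end` (scan end, min).
#' @seealso [default_frame_schedule()] for the 20-frame bolus-plus-infusion
#'   schedule used throughout.
#' @export
#' @examples
#' sched <- frame_schedule(c(0, 2, 4), c(2, 2, 2))
#' sched$mid
frame_schedule <- function(start, duration) {
  if (!is.numeric(start) || !is.numeric(duration))
    stop("'start' and 'duration' must be numeric")
  if (length(start) != length(duration))
    stop("'start' and 'duration' must have the same length")
  if (length(start) < 1L) stop("schedule must have at least one frame")
  if (anyNA(start) || anyNA(duration) || any(!is.finite(c(start, duration))))
    stop("schedule times must be finite")
  if (any(duration <= 0)) stop("frame durations must be > 0")
  if (start[1L] < 0) stop("first frame must not start before injection")
  if (length(start) > 1L) {
    if (any(diff(start) <= 0)) stop("frame start times must be strictly increasing")
    gaps <- start[-1L] - (start[-length(start)] + duration[-length(duration)])
    if (any(abs(gaps) > 1e-6))
      stop("frames must be contiguous and non-overlapping")
  }
  structure(
    list(start = as.numeric(start),
         duration = as.numeric(duration),
         mid = as.numeric(start + duration / 2),
         end = as.numeric(start[length(start)] + duration[length(duration)])),
    class = "frame_schedule")
}

#' Default 20-frame bolus-plus-infusion schedule
#'
#' The histogramming schedule used for the raclopride displacement protocol:
#' 8 x 2 min, 4 x 3 min, 2 x 4 min, 1 x 5 min, 1 x 6 min, 1 x 8 min and
#' 3 x 8.3 min, i.e. 20 frames covering 79.9 min.
#'
#' @return A [frame_schedule()] with 20 frames ending at 79.9 min.
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(2, 8), rep(3, 4), rep(4, 2), 5, 6, 8, rep(8.3, 3))
  frame_schedule(start = cumsum(c(0, dur[-length(dur)])), duration = dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, 0 - %.1f min\n",
              length(x$start), x$end))
  cat("durations (min):", paste(format(x$duration), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.frame_schedule <- function(x, ...) {
  data.frame(frame_start_min = x$start, frame_duration_min = x$duration,
             frame_mid_min = x$mid)
}

n_frames <- function(schedule) length(schedule$start)

same_schedule <- function(a, b, tol = 1e-9) {
  length(a$start) == length(b$start) &&
    all(abs(a$start - b$start) < tol) &&
    all(abs(a$duration - b$duration) < tol)
}
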