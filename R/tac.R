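#' Time--activity curve
#'
#' Radioactivity concentration per acquisition frame for one region or voxel.
#' The `role` records whether the curve is a target-tissue curve (C_T) or the
#' reference-region curve (C_R) used as the input of the reference tissue
#' model.
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector of activity concentrations (kBq/mL), one per
#'   frame.
#' @param role `"target"` or `"reference"`.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, role = c("target", "reference")) {
  role <- match.arg(role)
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule")
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule))
    stop("length(values) must equal the number of frames (",
         n_frames(schedule), ")")
  if (anyNA(values) || any(!is.finite(values)))
    stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values, role = role),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("%s TAC: %d frames, 0 - %.1f min, range %.3g - %.3g kBq/mL\n",
              x$role, n_frames(x$schedule), x$schedule$end,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write a TAC to CSV
#'
#' Serializes the curve together with its frame schedule, one row per frame,
#' columns `frame_start_min`, `frame_duration_min`, `activity_kBq_per_mL`.
#'
#' @param x a [tac()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(frame_start_min = x$schedule$start,
                   frame_duration_min = x$schedule$duration,
                   activity_kBq_per_mL = x$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a TAC from CSV
#'
#' @param path file written by [write_tac_csv()].
#' @param role `"target"` or `"reference"`.
#' @return A [tac()].
#' @export
read_tac_csv <- function(path, role = c("target", "reference")) {
  df <- utils::read.csv(path)
  need <- c("frame_start_min", "frame_duration_min", "activity_kBq_per_mL")
  if (!all(need %in% names(df)))
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  tac(frame_schedule(df$frame_start_min, df$frame_duration_min),
      df$activity_kBq_per_mL, role = match.arg(role))
}
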