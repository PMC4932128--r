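#' Frame schedules for dynamic PET
#'
#' A frame schedule records, for each reconstructed frame, its start time and
#' duration in seconds from tracer injection. Frames must be contiguous and
#' non-overlapping.
#'
#' @param durations_s Numeric vector of frame durations in seconds (all > 0).
#' @param start_s Optional numeric vector of frame start times in seconds;
#'   defaults to the cumulative sum of the durations starting at 0.
#' @return A data frame of class `frame_schedule` with columns `frame_index`
#'   (1-based), `start_s`, `duration_s`, `mid_s` and `mid_min`.
#' @examples
#' sched <- frame_schedule(c(rep(10, 6), rep(20, 3)))
#' sum(sched$duration_s)
#' @export
frame_schedule <- function(durations_s, start_s = NULL) {
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) < 1L || any(!is.finite(durations_s)) ||
      any(durations_s <= 0)) {
    stop("all frame durations must be finite and > 0")
  }
  if (is.null(start_s)) {
    start_s <- cumsum(c(0, durations_s[-length(durations_s)]))
  } else {
    start_s <- as.numeric(start_s)
    if (length(start_s) != length(durations_s)) {
      stop("start_s and durations_s must have the same length")
    }
    gap <- start_s[-1] - (start_s[-length(start_s)] +
                            durations_s[-length(durations_s)])
    if (any(abs(gap) > 1e-9)) {
      stop("frames must be contiguous: start[i+1] == start[i] + duration[i]")
    }
  }
  out <- data.frame(
    frame_index = seq_along(durations_s),
    start_s     = start_s,
    duration_s  = durations_s
  )
  out$mid_s   <- out$start_s + out$duration_s / 2
  out$mid_min <- out$mid_s / 60
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' The 22-frame, 60-minute tau-tracer acquisition schedule
#'
#' Default dynamic acquisition emulated by the phantom generator:
#' 6 x 10 s, 3 x 20 s, 2 x 30 s, 2 x 60 s, 2 x 150 s, 4 x 300 s and
#' 3 x 600 s frames, 22 frames spanning 3600 s in total.
#'
#' @return A `frame_schedule` with 22 frames covering 0--3600 s.
#' @export
thk_frame_schedule <- function() {
  frame_schedule(c(rep(10, 6), rep(20, 3), rep(30, 2), rep(60, 2),
                   rep(150, 2), rep(300, 4), rep(600, 3)))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.0f s total (%.1f min)\n",
              nrow(x), sum(x$duration_s), sum(x$duration_s) / 60))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write a frame-timing sidecar table
#'
#' The sidecar is a tab-separated table with columns `frame_index`, `start_s`
#' and `duration_s`, one row per frame, accompanying a 4D image.
#'
#' @param schedule A `frame_schedule`.
#' @param path File path of the TSV.
#' @return `read_frame_timing` returns a `frame_schedule`;
#'   `write_frame_timing` returns `path` invisibly.
#' @export
write_frame_timing <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  utils::write.table(schedule[, c("frame_index", "start_s", "duration_s")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_timing
#' @export
read_frame_timing <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  frame_schedule(tab$duration_s, tab$start_s)
}

# Fractional overlap (in minutes) of each frame with a [t0, t1] minute window.
frame_window_overlap_min <- function(schedule, window_min) {
  stopifnot(length(window_min) == 2L, window_min[2] > window_min[1])
  f0 <- schedule$start_s / 60
  f1 <- (schedule$start_s + schedule$duration_s) / 60
  pmax(0, pmin(f1, window_min[2]) - pmax(f0, window_min[1]))
}
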