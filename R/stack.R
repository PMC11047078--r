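#' Image timeseries of one reporter
#'
#' A uniformly sampled grayscale image stack (time x rows x cols) for a
#' single reporter channel, e.g. PER2::LUC or Rbm3-Luc bioluminescence,
#' or jRCaMP1a calcium fluorescence.
#'
#' @param frames numeric 3-D array, dimensions time x rows x cols,
#'   nonnegative intensities; at least 2 frames.
#' @param frame_interval_h hours between consecutive frames (> 0).
#' @param channel label for the reporter channel.
#' @param t0_h time of the first frame, hours from recording start.
#' @param schedule optional [temperature_schedule()] attached to the stack.
#' @return a `frame_stack` object.
#' @export
frame_stack <- function(frames, frame_interval_h, channel = "reporter",
                        t0_h = 0, schedule = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stopf("frame_stack: frames must be a 3-D array (time x rows x cols)")
  }
  if (dim(frames)[1] < 2L) stopf("frame_stack: at least 2 frames required")
  if (!is.numeric(frame_interval_h) || frame_interval_h <= 0) {
    stopf("frame_stack: frame_interval_h must be > 0")
  }
  if (any(frames < 0)) stopf("frame_stack: intensities must be nonnegative")
  if (!is.null(schedule) && !inherits(schedule, "temperature_schedule")) {
    stopf("frame_stack: schedule must be a temperature_schedule or NULL")
  }
  structure(
    list(frames = frames, frame_interval_h = frame_interval_h,
         channel = channel, t0_h = t0_h, schedule = schedule),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack '%s': %d frames of %dx%d px, dt = %g h, %g h total>\n",
              x$channel, d[1], d[2], d[3], x$frame_interval_h,
              d[1] * x$frame_interval_h))
  invisible(x)
}

#' Frame timestamps of a stack
#'
#' @param stack a `frame_stack`.
#' @return numeric vector of frame times in hours from recording start.
#' @export
stack_times <- function(stack) {
  stack$t0_h + (seq_len(dim(stack$frames)[1]) - 1L) * stack$frame_interval_h
}

n_frames <- function(stack) dim(stack$frames)[1]
frame_shape <- function(stack) dim(stack$frames)[c(2L, 3L)]
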