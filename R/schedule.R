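#' Temperature schedule for a recording
#'
#' An ordered, contiguous, non-overlapping set of temperature epochs
#' partitioning the recording, as imposed by the incubation chamber
#' (e.g. 37 degC baseline, a step down to 32 degC for several days,
#' and a return to 37 degC).
#'
#' @param start_h numeric vector of epoch start times, hours from
#'   recording start. The first must be 0.
#' @param end_h numeric vector of epoch end times, hours. Each epoch's
#'   end must equal the next epoch's start.
#' @param temp_c numeric vector of chamber temperatures, degrees Celsius.
#' @return a `temperature_schedule`: a data.frame with columns
#'   `epoch`, `start_h`, `end_h`, `temp_c`.
#' @export
temperature_schedule <- function(start_h, end_h, temp_c) {
  n <- length(start_h)
  if (n == 0L) stopf("temperature_schedule: at least one epoch required")
  if (length(end_h) != n || length(temp_c) != n) {
    stopf("temperature_schedule: start_h, end_h, temp_c must have equal length")
  }
  if (start_h[1] != 0) stopf("temperature_schedule: first epoch must start at 0 h")
  if (any(end_h <= start_h)) stopf("temperature_schedule: each end_h must exceed its start_h")
  if (n > 1 && any(abs(start_h[-1] - end_h[-n]) > 1e-9)) {
    stopf("temperature_schedule: epochs must be contiguous (start of epoch i+1 = end of epoch i)")
  }
  structure(
    data.frame(epoch = seq_len(n), start_h = start_h, end_h = end_h, temp_c = temp_c),
    class = c("temperature_schedule", "data.frame")
  )
}

#' @export
print.temperature_schedule <- function(x, ...) {
  cat(sprintf("<temperature_schedule: %d epoch(s), 0-%g h>\n", nrow(x), max(x$end_h)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

n_epochs <- function(schedule) nrow(schedule)

# Epoch index for each time point (last epoch is closed on the right).
epoch_of <- function(times_h, schedule) {
  idx <- findInterval(times_h, schedule$start_h)
  idx[idx < 1L] <- 1L
  idx[times_h >= schedule$end_h[nrow(schedule)]] <- nrow(schedule)
  idx
}

schedule_duration <- function(schedule) max(schedule$end_h) - min(schedule$start_h)
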