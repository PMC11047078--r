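# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Convert phase hours to radians on a circle of given period
#'
#' @param hours phase values in hours.
#' @param period_h circle period in hours (default 24, circadian time).
#' @return angles in radians, wrapped to (-pi, pi].
#' @export
hours_to_radians <- function(hours, period_h = 24) {
  wrap_angle(2 * pi * hours / period_h)
}

#' Convert radians back to phase hours on a circle of given period
#'
#' @param rad angles in radians.
#' @param period_h circle period in hours.
#' @return phase hours in [0, period_h).
#' @export
radians_to_hours <- function(rad, period_h = 24) {
  (rad * period_h / (2 * pi)) %% period_h
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
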