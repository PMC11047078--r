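#' Per-epoch linear slope of min-max normalized expression
#'
#' The trace is min-max normalized over the full recording (largest
#' value 100%, smallest 0%), then an ordinary least-squares line is
#' fitted independently within each temperature epoch. The slope
#' (percent of dynamic range per hour) summarizes the overall change
#' in reporter dynamics evoked by the temperature step (e.g. sustained
#' Rbm3-Luc induction upon cooling).
#'
#' @param trace raw numeric trace spanning the schedule.
#' @param frame_interval_h sampling interval, hours.
#' @param schedule a [temperature_schedule()].
#' @param t0_h time of the first sample, hours.
#' @param transient_skip_h hours discarded after each temperature step
#'   before fitting (default 0: the line is fitted through all epoch
#'   frames).
#' @return data.frame, one row per epoch: `epoch`, `temp_c`,
#'   `slope_pct_per_h`, `intercept_pct`, `r2`, `n_frames_used`.
#' @export
epoch_slopes <- function(trace, frame_interval_h, schedule, t0_h = 0,
                         transient_skip_h = 0) {
  if (missing(schedule) || is.null(schedule)) {
    stopf("epoch_slopes: temperature schedule required")
  }
  if (diff(range(trace)) == 0) stopf("epoch_slopes: constant trace")
  times <- t0_h + (seq_along(trace) - 1L) * frame_interval_h
  if (max(times) + frame_interval_h < max(schedule$end_h) - 1e-9) {
    stopf("epoch_slopes: trace (%g h) does not span the schedule (%g h)",
          max(times) + frame_interval_h, max(schedule$end_h))
  }
  y <- normalize_series(trace, method = "minmax")

  out <- lapply(seq_len(nrow(schedule)), function(e) {
    skip <- if (e == 1L) 0 else transient_skip_h
    idx <- which(times >= schedule$start_h[e] + skip - 1e-9 &
                   times < schedule$end_h[e] - 1e-9)
    if (length(idx) < 3L) {
      stopf("epoch_slopes: epoch %d has %d frames; need >= 3", e, length(idx))
    }
    fit <- stats::lm(y[idx] ~ times[idx])
    data.frame(epoch = e, temp_c = schedule$temp_c[e],
               slope_pct_per_h = stats::coef(fit)[[2]],
               intercept_pct = stats::coef(fit)[[1]],
               r2 = suppressWarnings(summary(fit))$r.squared,
               n_frames_used = length(idx))
  })
  do.call(rbind, out)
}

#' Period change per epoch relative to the recording mean
#'
#' Each rhythmic epoch's fitted period minus the unweighted mean period
#' over rhythmic epochs; by construction the values sum to zero. This
#' is the Delta-period readout of temperature effects on periodicity.
#'
#' @param per_epoch_fits list of per-epoch records from
#'   [fit_per_epoch()].
#' @return data.frame: `epoch`, `temp_c`, `period_h`, `delta_period_h`.
#' @export
delta_period <- function(per_epoch_fits) {
  keep <- Filter(function(r) !is.null(r$fit) && isTRUE(r$fit$is_rhythmic),
                 per_epoch_fits)
  if (length(keep) < 2L) {
    stopf("delta_period: need >= 2 rhythmic epochs, got %d", length(keep))
  }
  per <- vapply(keep, function(r) r$fit$period_h, numeric(1))
  data.frame(epoch = vapply(keep, `[[`, numeric(1), "epoch"),
             temp_c = vapply(keep, `[[`, numeric(1), "temp_c"),
             period_h = per,
             delta_period_h = per - mean(per))
}

#' Relative oscillation amplitude (post / pre)
#'
#' Ratio of fitted amplitudes in a post window versus a pre (baseline)
#' window, the readout of amplitude loss after a treatment or
#' temperature change.
#'
#' @param pre_fit,post_fit `rhythm_fit` objects for the two windows.
#' @return dimensionless ratio.
#' @export
relative_amplitude <- function(pre_fit, post_fit) {
  if (is.na(pre_fit$amplitude) || is.na(post_fit$amplitude)) {
    stopf("relative_amplitude: both windows must carry a fitted amplitude")
  }
  if (!isTRUE(pre_fit$is_rhythmic)) {
    stopf("relative_amplitude: pre window is nonrhythmic")
  }
  if (pre_fit$amplitude <= 0) stopf("relative_amplitude: zero pre amplitude")
  post_fit$amplitude / pre_fit$amplitude
}

#' Cross-reporter regression of temperature-response slopes
#'
#' Regresses reporter-b epoch slopes on reporter-a epoch slopes across
#' slices (OLS), per temperature epoch and pooled, reporting the fit
#' line, R-squared and the regression F-test p-value. A strong shared
#' temperature response (e.g. neuronal calcium and Rbm3-Luc induction
#' upon cooling) yields high R2 / small p; ablating one reporter's
#' response collapses R2 toward zero.
#'
#' @param slopes_a,slopes_b paired numeric vectors of per-slice slopes
#'   (same slices, same order).
#' @param epoch optional factor/vector of epoch ids, one per element,
#'   for per-epoch regressions.
#' @return data.frame, one row per epoch plus a `"pooled"` row:
#'   `epoch`, `n`, `slope`, `intercept`, `r2`, `p`.
#' @export
cross_reporter_regression <- function(slopes_a, slopes_b, epoch = NULL) {
  if (length(slopes_a) != length(slopes_b)) {
    stopf("cross_reporter_regression: unpaired slopes (%d vs %d)",
          length(slopes_a), length(slopes_b))
  }
  one <- function(a, b, label) {
    if (length(a) < 3L) {
      stopf("cross_reporter_regression: epoch '%s' has n = %d < 3", label, length(a))
    }
    fit <- stats::lm(b ~ a)
    sm <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
    fs <- sm$fstatistic
    p <- if (is.null(fs)) NA_real_ else
      stats::pf(fs[[1]], fs[[2]], fs[[3]], lower.tail = FALSE)
    data.frame(epoch = label, n = length(a),
               slope = stats::coef(fit)[[2]],
               intercept = stats::coef(fit)[[1]],
               r2 = sm$r.squared, p = p)
  }
  rows <- list()
  if (!is.null(epoch)) {
    for (e in unique(epoch)) {
      sel <- epoch == e
      rows[[length(rows) + 1L]] <- one(slopes_a[sel], slopes_b[sel], as.character(e))
    }
  }
  rows[[length(rows) + 1L]] <- one(slopes_a, slopes_b, "pooled")
  do.call(rbind, rows)
}
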