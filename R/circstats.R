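#' A sample of phases or vector angles on the circle
#'
#' @param values angles in radians, or phase hours with `unit = "hours"`.
#' @param unit "radians" (default) or "hours".
#' @param period_h circle period used for the hours-to-radians mapping
#'   (`x = 2 pi phase_h / period_h`); default 24 h (circadian time).
#' @param source optional label, e.g. "cluster_phase" or "vector_angle".
#' @return a `phase_sample` with values wrapped to (-pi, pi].
#' @export
phase_sample <- function(values, unit = c("radians", "hours"), period_h = 24,
                         source = "cluster_phase") {
  unit <- match.arg(unit)
  if (!length(values)) stopf("phase_sample: empty sample")
  rad <- if (unit == "hours") hours_to_radians(values, period_h) else wrap_angle(values)
  structure(list(values_rad = rad, period_h = period_h, source = source,
                 n = length(rad)),
            class = "phase_sample")
}

as_phase_sample <- function(x, ...) {
  if (inherits(x, "phase_sample")) x else phase_sample(x, ...)
}

resultant_length <- function(rad) {
  sqrt(sum(sin(rad))^2 + sum(cos(rad))^2) / length(rad)
}

#' Circular variance of a phase sample
#'
#' `1 - Rbar`, where `Rbar = sqrt((sum sin x)^2 + (sum cos x)^2) / n`
#' is the mean resultant length: 0 for perfectly clustered angles, 1
#' for fully dispersed ones. This is the intercluster phase-dispersal
#' statistic applied to cluster peak phases and to wave-vector angles.
#'
#' @param sample a [phase_sample()] or numeric vector of radians.
#' @param ... passed to [phase_sample()] when `sample` is numeric.
#' @return circular variance in [0, 1].
#' @export
circular_variance <- function(sample, ...) {
  s <- as_phase_sample(sample, ...)
  v <- 1 - resultant_length(s$values_rad)
  min(max(v, 0), 1)
}

#' Circular mean (and SD) of a phase sample
#'
#' Mean direction `atan2(sum sin x, sum cos x)`, with the circular
#' standard deviation `sqrt(-2 ln Rbar)`. When the resultant length is
#' (numerically) zero the mean direction is undefined and flagged.
#'
#' @param sample a [phase_sample()] or numeric vector of radians.
#' @param ... passed to [phase_sample()] when `sample` is numeric.
#' @return list: `mean_rad`, `mean_h`, `sd_rad`, `sd_h`, `rbar`,
#'   `undefined`.
#' @export
circular_mean <- function(sample, ...) {
  s <- as_phase_sample(sample, ...)
  rad <- s$values_rad
  rbar <- resultant_length(rad)
  if (rbar < 1e-12) {
    return(list(mean_rad = NA_real_, mean_h = NA_real_, sd_rad = NA_real_,
                sd_h = NA_real_, rbar = rbar, undefined = TRUE))
  }
  m <- wrap_angle(atan2(sum(sin(rad)), sum(cos(rad))))
  sd_rad <- sqrt(-2 * log(min(rbar, 1)))
  list(mean_rad = m,
       mean_h = radians_to_hours(m, s$period_h),
       sd_rad = sd_rad,
       sd_h = sd_rad * s$period_h / (2 * pi),
       rbar = rbar, undefined = FALSE)
}

#' Mean and SD of cluster periods
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the fitted periods of rhythmic clusters; NR clusters are excluded.
#'
#' @param fits list of `rhythm_fit` objects (e.g. `result$fits`).
#' @return list: `mean_h`, `sd_h`, `n` (rhythmic fits used).
#' @export
period_dispersion <- function(fits) {
  per <- vapply(Filter(function(f) isTRUE(f$is_rhythmic), fits),
                `[[`, numeric(1), "period_h")
  if (length(per) < 2L) {
    stopf("period_dispersion: need >= 2 rhythmic fits, got %d", length(per))
  }
  list(mean_h = mean(per), sd_h = stats::sd(per), n = length(per))
}

#' Intercluster circular statistics of a cluster result
#'
#' Convenience wrapper computing the Fig. 5-style per-slice readouts:
#' intercluster circular variance of cluster peak phases (on a common
#' 24 h circadian circle), mean cluster period and period SD.
#'
#' @param result a `cluster_result`.
#' @param period_h circle period for the phase mapping (default 24).
#' @return one-row data.frame: `intercluster_circvar`, `period_mean_h`,
#'   `period_sd_h`, `n_rhythmic_clusters`.
#' @export
cluster_circular_stats <- function(result, period_h = 24) {
  keep <- which(!result$is_nr)
  circvar <- NA_real_
  if (length(keep) >= 1L) {
    ph <- vapply(result$fits[keep], `[[`, numeric(1), "circ_phase_h")
    circvar <- circular_variance(phase_sample(ph, unit = "hours",
                                              period_h = period_h))
  }
  pd <- if (length(keep) >= 2L) period_dispersion(result$fits) else
    list(mean_h = NA_real_, sd_h = NA_real_)
  data.frame(intercluster_circvar = circvar,
             period_mean_h = pd$mean_h, period_sd_h = pd$sd_h,
             n_rhythmic_clusters = length(keep))
}
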