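nonrhythmic_fit <- function(n, reason = "no_spectral_peak") {
  structure(list(period_h = NA_real_, amplitude = NA_real_,
                 abs_phase_h = NA_real_, circ_phase_h = NA_real_,
                 rae = Inf, gof = 0, is_rhythmic = FALSE, offset = NA_real_,
                 n = n, diagnostic = reason),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (!x$is_rhythmic) {
    cat(sprintf("<rhythm_fit: nonrhythmic (%s)>\n",
                if (is.null(x$diagnostic)) "rae above threshold" else x$diagnostic))
  } else {
    cat(sprintf(
      "<rhythm_fit: period %.2f h, amplitude %.3g, peak at %.2f h (CT %.2f), RAE %.3f, GOF %.3f>\n",
      x$period_h, x$amplitude, x$abs_phase_h, x$circ_phase_h, x$rae, x$gof))
  }
  invisible(x)
}

# FFT periodogram seed: dominant in-band period, amplitude and peak time.
fft_seed <- function(y, dt, band_h) {
  n <- length(y)
  nfft <- 2^ceiling(log2(max(n * 8, 256)))
  Y <- stats::fft(c(y, rep(0, nfft - n)))
  k <- seq_len(nfft %/% 2)          # positive frequencies, excluding DC
  freq <- k / (nfft * dt)
  per <- 1 / freq
  inband <- which(per >= band_h[1] & per <= band_h[2])
  if (!length(inband)) return(NULL)
  pw <- Mod(Y[k + 1L])^2
  best <- inband[which.max(pw[inband])]
  if (pw[best] <= 0) return(NULL)
  tau0 <- per[best]
  amp0 <- 2 * Mod(Y[best + 1L]) / n
  # y ~ A cos(2 pi f (t - phi)) gives Arg(Y) = -2 pi f phi
  phi0 <- (-Arg(Y[best + 1L]) / (2 * pi * freq[best])) %% tau0
  list(tau = tau0, amp = amp0, phi = phi0)
}

#' Fit the dominant circadian sinewave of a detrended trace
#'
#' Spectral seeding followed by nonlinear least squares: (i) a
#' zero-padded FFT periodogram proposes the highest-power period inside
#' the circadian search band; (ii) Levenberg-Marquardt refines
#' `y(t) = A cos(2 pi (t - phi) / tau) + c` over (A, phi, tau, c);
#' (iii) rhythmicity is classified by the relative amplitude error
#' (RAE), the 95% confidence half-width of A divided by A.
#'
#' Phase is reported in both conventions: `abs_phase_h`, the first peak
#' time of the fitted cosine after the window start ("absolute phase to
#' zero", used for cluster peak times to control for period effects),
#' and `circ_phase_h`, the same peak mapped onto a 24 h circadian scale
#' (`abs_phase_h * 24 / period_h` mod 24, "circadian phase to zero").
#'
#' @param trace detrended numeric trace (mean approximately 0).
#' @param frame_interval_h sampling interval, hours.
#' @param band_h circadian period search band, hours (default 16-32 h,
#'   wide enough for Cry-mutant short periods and cooling-lengthened
#'   periods).
#' @param rae_threshold rhythmicity criterion: rhythmic iff
#'   RAE <= threshold and the period lies in `band_h` (default 0.3).
#' @param times optional explicit time vector, hours.
#' @return a `rhythm_fit`: period_h, amplitude, abs_phase_h,
#'   circ_phase_h, rae, gof (1 - SSR/SST), is_rhythmic, offset, n.
#'   A flat spectrum or solver failure yields a nonrhythmic result
#'   with a `diagnostic` field, not an error.
#' @export
fit_dominant_sinewave <- function(trace, frame_interval_h, band_h = c(16, 32),
                                  rae_threshold = 0.3, times = NULL) {
  n <- length(trace)
  if (is.null(times)) times <- (seq_len(n) - 1L) * frame_interval_h
  duration <- max(times) - min(times)
  if (duration < 2 * band_h[2]) {
    stopf("fit_dominant_sinewave: trace spans %g h; need >= 2 x band upper bound (%g h)",
          duration, 2 * band_h[2])
  }
  tt <- times - min(times)
  y <- as.numeric(trace)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(nonrhythmic_fit(n, "constant_trace"))

  seed <- fft_seed(y - mean(y), frame_interval_h, band_h)
  if (is.null(seed)) return(nonrhythmic_fit(n, "no_spectral_peak"))

  residual_fn <- function(p) {
    y - (p[1] * cos(2 * pi * (tt - p[2]) / p[3]) + p[4])
  }
  # analytic model Jacobian; residual Jacobian is its negative
  model_jac <- function(p) {
    w <- 2 * pi / p[3]
    arg <- w * (tt - p[2])
    s <- sin(arg)
    cbind(cos(arg), p[1] * s * w, p[1] * s * 2 * pi * (tt - p[2]) / p[3]^2, 1)
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = c(seed$amp, seed$phi, seed$tau, mean(y)),
                       fn = residual_fn, jac = function(p) -model_jac(p),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(out) || out$info %in% c(0L, 5L)) {
    return(nonrhythmic_fit(n, "solver_failure"))
  }

  A <- out$par[1]; phi <- out$par[2]; tau <- out$par[3]; c0 <- out$par[4]
  if (!is.finite(tau) || tau <= 0) return(nonrhythmic_fit(n, "solver_failure"))
  if (A < 0) {          # flip the sign into the phase
    A <- -A
    phi <- phi + tau / 2
  }
  abs_phase <- phi %% tau
  circ_phase <- (abs_phase * 24 / tau) %% 24

  # linearized covariance of A: sigma^2 (J'J)^{-1} at the solution
  dof <- n - 4L
  ssr <- out$deviance
  se_A <- tryCatch({
    J <- model_jac(out$par)
    sqrt(ssr / dof * solve(crossprod(J))[1, 1])
  }, error = function(e) NA_real_)
  rae <- if (is.finite(se_A) && A > 0) {
    stats::qt(0.975, dof) * se_A / A
  } else Inf
  gof <- max(0, 1 - ssr / sst)
  rhythmic <- is.finite(rae) && rae <= rae_threshold &&
    tau >= band_h[1] && tau <= band_h[2] && A > 0

  structure(list(period_h = tau, amplitude = A, abs_phase_h = abs_phase,
                 circ_phase_h = circ_phase, rae = rae, gof = gof,
                 is_rhythmic = rhythmic, offset = c0, n = n,
                 diagnostic = NULL),
            class = "rhythm_fit")
}

#' Per-epoch sinewave fits under a temperature schedule
#'
#' Each temperature epoch is analysed independently: the first
#' `transient_skip_h` hours after a temperature step are discarded (the
#' acute response is not an oscillation of interest), the windowed
#' trace is cubic-detrended, and the dominant sinewave fitted. Epochs
#' whose post-skip window is shorter than twice the band upper bound
#' are flagged `too_short` and carry no fit.
#'
#' @param trace raw (not detrended) numeric trace over the recording.
#' @param frame_interval_h sampling interval, hours.
#' @param schedule a [temperature_schedule()].
#' @param transient_skip_h hours discarded after each temperature step
#'   (not applied to the first epoch; the recording start is not a
#'   step). Default 12.
#' @param band_h,rae_threshold passed to [fit_dominant_sinewave()].
#' @param t0_h time of the first sample, hours.
#' @return list of per-epoch records: `epoch`, `temp_c`, `start_h`,
#'   `end_h`, `too_short`, `fit` (a `rhythm_fit` or NULL).
#' @export
fit_per_epoch <- function(trace, frame_interval_h, schedule,
                          transient_skip_h = 12, band_h = c(16, 32),
                          rae_threshold = 0.3, t0_h = 0) {
  if (missing(schedule) || is.null(schedule)) {
    stopf("fit_per_epoch: temperature schedule required")
  }
  times <- t0_h + (seq_along(trace) - 1L) * frame_interval_h
  lapply(seq_len(nrow(schedule)), function(e) {
    skip <- if (e == 1L) 0 else transient_skip_h
    w0 <- schedule$start_h[e] + skip
    w1 <- schedule$end_h[e]
    idx <- which(times >= w0 - 1e-9 & times <= w1 + 1e-9)
    rec <- list(epoch = e, temp_c = schedule$temp_c[e],
                start_h = schedule$start_h[e], end_h = schedule$end_h[e],
                too_short = FALSE, fit = NULL)
    if (length(idx) < 5L ||
        (length(idx) - 1L) * frame_interval_h < 2 * band_h[2]) {
      rec$too_short <- TRUE
      return(rec)
    }
    det <- cubic_detrend(trace[idx], times = times[idx])
    rec$fit <- fit_dominant_sinewave(det, frame_interval_h, band_h = band_h,
                                     rae_threshold = rae_threshold,
                                     times = times[idx])
    rec
  })
}

#' Circular peak-phase offset between two rhythmic fits
#'
#' Difference of circadian phases on the 24 h circle, in (-12, +12] h;
#' positive means `fit_b` peaks after `fit_a` (e.g. a luciferase
#' reporter peaking ~4 h after the calcium reporter).
#'
#' @param fit_a,fit_b rhythmic `rhythm_fit` objects.
#' @return signed offset in hours.
#' @export
phase_offset <- function(fit_a, fit_b) {
  if (!isTRUE(fit_a$is_rhythmic) || !isTRUE(fit_b$is_rhythmic)) {
    stopf("phase_offset: both fits must be rhythmic")
  }
  d <- (fit_b$circ_phase_h - fit_a$circ_phase_h) %% 24
  if (d > 12) d <- d - 24
  d
}
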