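# Shared fixtures: small, fast synthetic stacks built in code.

# Noise-free gaussian stack (sd = 0) with convenient defaults.
quiet_params <- function(...) {
  synth_params(noise_model = "gaussian", gaussian_sd = 0,
               nonrhythmic_border_frac = 0, ...)
}

# A small uniform-intensity stack for I/O and tiling tests.
flat_stack <- function(value = 5, nf = 20L, nr = 12L, nc = 12L, dt = 0.5) {
  frame_stack(array(value, dim = c(nf, nr, nc)), dt, channel = "flat")
}

# ROI-level ground-truth labels: planted cluster band at each tile center.
roi_truth_labels <- function(rois, truth) {
  ctr <- rois$roi_centers + 1L   # 0-based centers -> 1-based indices
  truth$cluster_labels[cbind(ctr[, 1], ctr[, 2])]
}

roi_truth_phases <- function(rois, truth) {
  ctr <- rois$roi_centers + 1L
  truth$phase_map_h[cbind(ctr[, 1], ctr[, 2])]
}

# Standard analysis front-end: detrend, tile, z-score.
detrended_rois <- function(stack, mask, window_h = 24.5) {
  md <- moving_average_detrend(stack, window_h = window_h)
  rois <- tile_rois(md, mask)
  rois$series <- normalize_series(rois$series)
  rois
}

# Independent brute-force oracle for the sinewave fit: grid search over
# period at `step` resolution with exact linear least squares for the
# cosine/sine components at each candidate period.
grid_search_sinewave <- function(y, times, band = c(16, 32), step = 0.01) {
  taus <- seq(band[1], band[2], by = step)
  best <- NULL
  for (tau in taus) {
    X <- cbind(1, cos(2 * pi * times / tau), sin(2 * pi * times / tau))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      b <- unname(fit$coefficients)
      amp <- sqrt(b[2]^2 + b[3]^2)
      phi <- (atan2(b[3], b[2]) * tau / (2 * pi)) %% tau
      best <- list(rss = rss, tau = tau, amp = amp, phi = phi)
    }
  }
  best
}

# Shortest distance between two phases on a circle of given period.
circ_dist_h <- function(a, b, period) {
  d <- abs((a - b) %% period)
  pmin(d, period - d)
}

# Von Mises sampler (Best & Fisher 1979 rejection scheme), used as an
# independent source of circular samples with known concentration.
rvonmises <- function(n, mu = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# Minimal stand-in rhythm_fit for statistics-level tests.
fake_fit <- function(period_h, amplitude = 1, abs_phase_h = 0,
                     rhythmic = TRUE) {
  structure(list(period_h = period_h, amplitude = amplitude,
                 abs_phase_h = abs_phase_h,
                 circ_phase_h = (abs_phase_h * 24 / period_h) %% 24,
                 rae = if (rhythmic) 0.05 else Inf, gof = 0.99,
                 is_rhythmic = rhythmic, offset = 0, n = 100L,
                 diagnostic = NULL),
            class = "rhythm_fit")
}
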