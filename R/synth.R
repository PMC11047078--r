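#' Parameters for the synthetic SCN stack generator
#'
#' Describes an SCN-like recording: an elliptical tissue region of
#' per-pixel circadian oscillators with a linear spatial phase gradient
#' (the dorsomedial-to-ventrolateral wave analogue), a slowly varying
#' baseline (reporter decay / temperature-step slope changes), per-epoch
#' period and amplitude modulation by chamber temperature, photon-count
#' noise, a rim of nonrhythmic pixels, and optionally a second reporter
#' whose peak lags the first by a fixed number of hours.
#'
#' Per-epoch parameters (`period_shift_per_epoch_h`,
#' `amplitude_scale_per_epoch`, `baseline_slope_per_epoch`,
#' `photon_yield_per_epoch`) are recycled to the number of epochs in
#' `temperature_schedule`.
#'
#' @param grid_shape integer (rows, cols) of the image grid.
#' @param n_frames number of frames.
#' @param frame_interval_h hours between frames (default 0.5 h).
#' @param baseline_period_h free-running period at baseline temperature,
#'   hours.
#' @param period_shift_per_epoch_h additive period change per epoch,
#'   hours (e.g. cooling-induced lengthening).
#' @param amplitude_frac planted relative oscillation amplitude
#'   (peak-to-mean ratio), in [0, 1].
#' @param amplitude_scale_per_epoch multiplicative amplitude factor per
#'   epoch.
#' @param baseline_level mean photon counts per frame in tissue.
#' @param baseline_slope_per_epoch baseline drift per epoch, percent of
#'   `baseline_level` per hour.
#' @param photon_yield_per_epoch multiplicative photon-yield factor per
#'   epoch (luciferase photon emission itself depends on temperature).
#' @param wave_angle_rad direction along which phase increases, radians
#'   (0 = left-to-right across columns, pi/2 = top-to-bottom across rows).
#' @param phase_span_h total phase lag across the tissue along the wave
#'   direction, hours.
#' @param reporter_lag_h peak lag of the second reporter, hours.
#' @param n_reporters 1 or 2 co-registered reporters.
#' @param channels channel labels, length `n_reporters`. For dual
#'   runs the default is `c("ca", "luc")`: the lagged second reporter
#'   plays the luciferase peaking after the calcium signal.
#' @param noise_model "poisson" (photon counting, bioluminescence-like)
#'   or "gaussian" (camera read noise, fluorescence-like); may be a
#'   vector of length `n_reporters`.
#' @param gaussian_sd noise SD for the gaussian model, intensity units.
#' @param nonrhythmic_border_frac fraction of tissue pixels (outermost
#'   rim) with zero planted amplitude, in [0, 1).
#' @param n_phase_bands number of ground-truth phase bands (clustering
#'   oracle), default 5.
#' @param quantize_phase_bands if TRUE, planted phases are snapped to
#'   the mean of their phase band, planting `n_phase_bands` discrete
#'   phase groups instead of a continuous ramp — the unambiguous
#'   ground truth for clustering-recovery tests. Default FALSE
#'   (continuous wave).
#' @param seed integer RNG seed.
#' @param temperature_schedule a [temperature_schedule()] spanning the
#'   recording exactly; default a single 37 degC epoch.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(grid_shape = c(64L, 64L),
                         n_frames = 240L,
                         frame_interval_h = 0.5,
                         baseline_period_h = 24,
                         period_shift_per_epoch_h = 0,
                         amplitude_frac = 0.5,
                         amplitude_scale_per_epoch = 1,
                         baseline_level = 1000,
                         baseline_slope_per_epoch = 0,
                         photon_yield_per_epoch = 1,
                         wave_angle_rad = 0,
                         phase_span_h = 8,
                         reporter_lag_h = 4,
                         n_reporters = 1L,
                         channels = if (n_reporters == 2L) c("ca", "luc") else "luc",
                         noise_model = "poisson",
                         gaussian_sd = 10,
                         nonrhythmic_border_frac = 0.05,
                         n_phase_bands = 5L,
                         quantize_phase_bands = FALSE,
                         seed = 1L,
                         temperature_schedule = NULL) {
  total_h <- n_frames * frame_interval_h
  if (is.null(temperature_schedule)) {
    temperature_schedule <- temperature_schedule(0, total_h, 37)
  }
  p <- list(grid_shape = as.integer(grid_shape), n_frames = as.integer(n_frames),
            frame_interval_h = frame_interval_h,
            baseline_period_h = baseline_period_h,
            period_shift_per_epoch_h = period_shift_per_epoch_h,
            amplitude_frac = amplitude_frac,
            amplitude_scale_per_epoch = amplitude_scale_per_epoch,
            baseline_level = baseline_level,
            baseline_slope_per_epoch = baseline_slope_per_epoch,
            photon_yield_per_epoch = photon_yield_per_epoch,
            wave_angle_rad = wave_angle_rad, phase_span_h = phase_span_h,
            reporter_lag_h = reporter_lag_h, n_reporters = as.integer(n_reporters),
            channels = channels, noise_model = noise_model,
            gaussian_sd = gaussian_sd,
            nonrhythmic_border_frac = nonrhythmic_border_frac,
            n_phase_bands = as.integer(n_phase_bands),
            quantize_phase_bands = isTRUE(quantize_phase_bands),
            seed = as.integer(seed),
            temperature_schedule = temperature_schedule)
  validate_synth_params(p)
  class(p) <- "synth_params"
  p
}

validate_synth_params <- function(p) {
  if (length(p$grid_shape) != 2L || any(p$grid_shape < 4L)) {
    stopf("synth_params: grid_shape must be (rows, cols), each >= 4")
  }
  total_h <- p$n_frames * p$frame_interval_h
  if (total_h < 3 * p$baseline_period_h) {
    stopf("synth_params: n_frames x frame_interval_h (%g h) must cover >= 3 x baseline_period_h (%g h); stable fitting needs >= 3 cycles",
          total_h, 3 * p$baseline_period_h)
  }
  if (p$amplitude_frac < 0 || p$amplitude_frac > 1) {
    stopf("synth_params: amplitude_frac must lie in [0, 1]")
  }
  if (p$nonrhythmic_border_frac < 0 || p$nonrhythmic_border_frac >= 1) {
    stopf("synth_params: nonrhythmic_border_frac must lie in [0, 1)")
  }
  sch <- p$temperature_schedule
  if (!inherits(sch, "temperature_schedule")) {
    stopf("synth_params: temperature_schedule must be a temperature_schedule")
  }
  if (abs(sch$start_h[1]) > 1e-9 || abs(max(sch$end_h) - total_h) > 1e-9) {
    stopf("synth_params: temperature_schedule must span [0, %g] h exactly", total_h)
  }
  if (!all(p$noise_model %in% c("poisson", "gaussian"))) {
    stopf("synth_params: noise_model must be 'poisson' or 'gaussian'")
  }
  if (!p$n_reporters %in% c(1L, 2L)) stopf("synth_params: n_reporters must be 1 or 2")
  ne <- n_epochs(sch)
  for (f in c("period_shift_per_epoch_h", "amplitude_scale_per_epoch",
              "baseline_slope_per_epoch", "photon_yield_per_epoch")) {
    if (!length(p[[f]]) %in% c(1L, ne)) {
      stopf("synth_params: %s must have length 1 or %d (one per epoch)", f, ne)
    }
  }
  invisible(p)
}

# Elliptical tissue geometry and per-pixel planted parameters.
synth_geometry <- function(p) {
  nr <- p$grid_shape[1]; nc <- p$grid_shape[2]
  r0 <- matrix(0:(nr - 1), nr, nc)            # 0-based row coordinate
  c0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  ay <- 0.42 * nr; ax <- 0.42 * nc
  rad2 <- ((r0 - cy) / ay)^2 + ((c0 - cx) / ax)^2
  tissue <- rad2 <= 1

  rhythmic <- tissue
  if (p$nonrhythmic_border_frac > 0) {
    thr <- stats::quantile(rad2[tissue], 1 - p$nonrhythmic_border_frac,
                           names = FALSE, type = 7)
    rhythmic <- tissue & (rad2 <= thr)
  }

  u <- c0 * cos(p$wave_angle_rad) + r0 * sin(p$wave_angle_rad)
  ut <- u[tissue]
  unorm <- matrix(NA_real_, nr, nc)
  rng <- diff(range(ut))
  unorm[tissue] <- if (rng > 0) (u[tissue] - min(ut)) / rng else 0

  phase <- matrix(NA_real_, nr, nc)
  phase[tissue] <- (p$phase_span_h * unorm[tissue]) %% p$baseline_period_h

  labels <- matrix(NA_integer_, nr, nc)
  ph_r <- phase[rhythmic]
  if (length(unique(ph_r)) < p$n_phase_bands) {
    labels[rhythmic] <- 1L
  } else {
    br <- stats::quantile(ph_r, probs = seq(0, 1, length.out = p$n_phase_bands + 1),
                          names = FALSE, type = 7)
    br <- unique(br)
    labels[rhythmic] <- as.integer(cut(ph_r, breaks = br, include.lowest = TRUE))
  }

  if (isTRUE(p$quantize_phase_bands) && any(!is.na(labels))) {
    # discrete plant: every pixel of a band oscillates at the band's
    # mean phase, so the k-band structure is the exact generative truth
    for (b in sort(unique(labels[!is.na(labels)]))) {
      sel <- !is.na(labels) & labels == b
      phase[sel] <- mean(phase[sel])
    }
  }

  list(tissue = tissue, rhythmic = rhythmic, phase = phase, labels = labels)
}

# Per-epoch piecewise description evaluated at each frame time.
synth_timecourse <- function(p) {
  sch <- p$temperature_schedule
  ne <- n_epochs(sch)
  tau <- p$baseline_period_h + rep_len(p$period_shift_per_epoch_h, ne)
  scale <- rep_len(p$amplitude_scale_per_epoch, ne)
  slope <- rep_len(p$baseline_slope_per_epoch, ne)   # %/h of baseline_level
  yield <- rep_len(p$photon_yield_per_epoch, ne)
  dur <- sch$end_h - sch$start_h

  # Phase accumulates continuously across epoch boundaries.
  theta_start <- cumsum(c(0, 2 * pi * dur / tau))[seq_len(ne)]
  rate <- slope / 100 * p$baseline_level
  b_start <- cumsum(c(p$baseline_level, rate * dur))[seq_len(ne)]

  times <- (seq_len(p$n_frames) - 1L) * p$frame_interval_h
  e <- epoch_of(times, sch)
  theta <- theta_start[e] + 2 * pi * (times - sch$start_h[e]) / tau[e]
  baseline <- b_start[e] + rate[e] * (times - sch$start_h[e])
  if (any(baseline <= 0)) {
    stopf("synth_params: baseline_slope_per_epoch drives the baseline nonpositive")
  }
  list(times = times, epoch = e, theta = theta, baseline = baseline,
       amp_scale = scale[e], yield = yield[e], tau = tau, slope = slope)
}

#' Generate a synthetic SCN-like image stack with known ground truth
#'
#' Pixel intensity before noise is
#' `yield(epoch) * baseline(t, epoch) * (1 + a(pixel, epoch) *
#' cos(theta(t) - 2 pi phase(pixel) / tau1))`, with phase accumulating
#' continuously across temperature epochs of differing period. Pixels
#' outside the elliptical tissue mask carry background noise only. The
#' optional second reporter shares the tissue phase map shifted by
#' `reporter_lag_h` and draws its own noise.
#'
#' @param params a [synth_params()] object.
#' @return list with `stacks` (list of one or two [frame_stack()]s),
#'   `stack` (the first, for convenience) and `truth`, a `ground_truth`
#'   list holding `phase_map_h`, `period_per_epoch_h`, `cluster_labels`,
#'   `wave_angle_rad`, `epoch_slopes`, `rhythmic_mask`, `tissue_mask`
#'   and the generator provenance (`seed`, `params`).
#' @export
generate_stack <- function(params) {
  p <- if (inherits(params, "synth_params")) params else do.call(synth_params, params)
  validate_synth_params(p)
  geo <- synth_geometry(p)
  tc <- synth_timecourse(p)
  nr <- p$grid_shape[1]; nc <- p$grid_shape[2]
  bg_level <- 0.02 * p$baseline_level
  noise <- rep_len(p$noise_model, p$n_reporters)
  gsd <- rep_len(p$gaussian_sd, p$n_reporters)

  amp <- matrix(0, nr, nc)
  amp[geo$rhythmic] <- p$amplitude_frac

  stacks <- with_seed(p$seed, {
    lapply(seq_len(p$n_reporters), function(rep_i) {
      lag <- if (rep_i == 2L) p$reporter_lag_h else 0
      psi <- matrix(0, nr, nc)
      psi[geo$tissue] <- 2 * pi * (geo$phase[geo$tissue] + lag) / tc$tau[1]
      frames <- array(0, dim = c(p$n_frames, nr, nc))
      for (i in seq_len(p$n_frames)) {
        expected <- matrix(bg_level, nr, nc)
        osc <- 1 + amp[geo$tissue] * tc$amp_scale[i] *
          cos(tc$theta[i] - psi[geo$tissue])
        expected[geo$tissue] <- tc$yield[i] * tc$baseline[i] * osc
        frames[i, , ] <- if (noise[rep_i] == "poisson") {
          stats::rpois(nr * nc, lambda = expected)
        } else {
          pmax(expected + stats::rnorm(nr * nc, sd = gsd[rep_i]), 0)
        }
      }
      frame_stack(frames, p$frame_interval_h, channel = p$channels[rep_i],
                  schedule = p$temperature_schedule)
    })
  })

  rhythmic_mask <- geo$rhythmic & (p$amplitude_frac > 0)

  truth <- structure(list(
    phase_map_h = geo$phase,
    period_per_epoch_h = tc$tau,
    cluster_labels = geo$labels,
    wave_angle_rad = p$wave_angle_rad,
    epoch_slopes = rep_len(p$baseline_slope_per_epoch, n_epochs(p$temperature_schedule)),
    rhythmic_mask = rhythmic_mask,
    tissue_mask = geo$tissue,
    reporter_lag_h = if (p$n_reporters == 2L) p$reporter_lag_h else NA_real_,
    seed = p$seed,
    params = p
  ), class = "ground_truth")

  list(stacks = stacks, stack = stacks[[1]], truth = truth)
}

#' Write a frame stack as a 16-bit multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame, in time order, 16-bit unsigned grayscale.
#' The sidecar records frame_interval_h, channel, t0_h, the temperature
#' schedule (if attached) and an optional seed, so that a stack on disk
#' is self-describing.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @param sidecar_path output JSON path; default `path` with a `.json`
#'   extension appended.
#' @param seed optional integer recorded in the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path, sidecar_path = NULL, seed = NULL) {
  if (!inherits(stack, "frame_stack")) stopf("write_stack: not a frame_stack")
  nf <- n_frames(stack)
  if (nf == 0L) stopf("write_stack: empty stack")
  vals <- round(stack$frames)
  over <- which(apply(vals > 65535, 1, any))
  if (length(over)) {
    stopf("write_stack: frame %d exceeds the 16-bit range after scaling", over[1])
  }
  pages <- lapply(seq_len(nf), function(i) vals[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)

  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  meta <- list(frame_interval_h = stack$frame_interval_h,
               channel = stack$channel, t0_h = stack$t0_h)
  if (!is.null(stack$schedule)) {
    meta$temperature_epochs <- lapply(seq_len(nrow(stack$schedule)), function(i) {
      list(start_h = stack$schedule$start_h[i], end_h = stack$schedule$end_h[i],
           temp_c = stack$schedule$temp_c[i])
    })
  }
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' Write generator ground truth as JSON plus per-pixel CSV maps
#'
#' @param truth a `ground_truth` from [generate_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- list(period_per_epoch_h = truth$period_per_epoch_h,
                  wave_angle_rad = truth$wave_angle_rad,
                  epoch_slopes = truth$epoch_slopes,
                  reporter_lag_h = truth$reporter_lag_h,
                  seed = truth$seed)
  jsonlite::write_json(scalars, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(truth$phase_map_h, file.path(dir, "phase_map_h.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$cluster_labels, file.path(dir, "cluster_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$rhythmic_mask * 1L, file.path(dir, "rhythmic_mask.csv"),
                   row.names = FALSE)
  invisible(dir)
}
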