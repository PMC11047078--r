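#' Read a multi-page TIFF stack with its JSON sidecar
#'
#' Frames are returned in page (= time) order. The frame interval must
#' be present in the sidecar; the function refuses to guess it. A
#' temperature schedule in the sidecar is attached to the stack;
#' schedule-dependent operations fail later if it is absent.
#'
#' @param path multi-page TIFF written by [write_stack()] or equivalent.
#' @param sidecar_path JSON sidecar; default `path` + ".json".
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stopf("read_stack: no such file: %s", path)
  if (!file.exists(sidecar_path)) stopf("read_stack: missing sidecar: %s", sidecar_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp)) {
      stopf("read_stack: page %d has shape %s, expected %s", i,
            paste(dim(pages[[i]]), collapse = "x"), paste(shp, collapse = "x"))
    }
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$frame_interval_h)) {
    stopf("read_stack: sidecar lacks frame_interval_h; refusing to guess")
  }
  frames <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * 65535
  schedule <- NULL
  te <- meta$temperature_epochs
  if (!is.null(te) && length(te)) {
    te <- as.data.frame(te)
    schedule <- temperature_schedule(te$start_h, te$end_h, te$temp_c)
  }
  frame_stack(frames, meta$frame_interval_h,
              channel = if (is.null(meta$channel)) "reporter" else meta$channel,
              t0_h = if (is.null(meta$t0_h)) 0 else meta$t0_h,
              schedule = schedule)
}

# Centered moving average with a symmetrically shrinking window at the
# edges (no padding; the window never extends beyond recorded frames).
moving_average_matrix <- function(x, win_frames) {
  n <- nrow(x)
  half <- (win_frames - 1L) %/% 2L
  cs <- rbind(0, apply(x, 2, cumsum))
  out <- x
  for (t in seq_len(n)) {
    h <- min(half, t - 1L, n - t)
    out[t, ] <- (cs[t + h + 1L, ] - cs[t - h, ]) / (2L * h + 1L)
  }
  out
}

#' Moving-average detrend of an image stack or trace
#'
#' Subtracts, per pixel, a centered moving average of window `window_h`
#' (default 24.5 h, just over one circadian cycle, so the running mean
#' tracks baseline drift while averaging out the oscillation). The
#' window length in frames is rounded and forced odd; at the recording
#' edges it shrinks symmetrically to the available frames.
#'
#' @param x a [frame_stack()] or a numeric vector/matrix (rows = time).
#' @param window_h moving-average window in hours.
#' @param frame_interval_h required when `x` is not a `frame_stack`.
#' @return same type as `x`, detrended.
#' @export
moving_average_detrend <- function(x, window_h = 24.5, frame_interval_h = NULL) {
  if (inherits(x, "frame_stack")) {
    dt <- x$frame_interval_h
    n <- n_frames(x)
  } else {
    if (is.null(frame_interval_h)) {
      stopf("moving_average_detrend: frame_interval_h required for plain input")
    }
    dt <- frame_interval_h
    n <- if (is.matrix(x)) nrow(x) else length(x)
  }
  if (window_h > n * dt) {
    stopf("moving_average_detrend: window (%g h) is longer than the recording (%g h)",
          window_h, n * dt)
  }
  win <- as.integer(round(window_h / dt))
  if (win %% 2L == 0L) win <- win + 1L
  win <- max(win, 1L)
  if (inherits(x, "frame_stack")) {
    d <- dim(x$frames)
    m <- matrix(x$frames, nrow = d[1])
    det <- m - moving_average_matrix(m, win)
    out <- x
    # detrended intensities are residuals and may be negative; bypass the
    # nonnegativity check of the constructor on purpose
    out$frames <- array(det, dim = d)
    out
  } else if (is.matrix(x)) {
    x - moving_average_matrix(x, win)
  } else {
    drop(x - moving_average_matrix(cbind(x), win))
  }
}

#' Cubic detrend of a timeseries
#'
#' Subtracts the least-squares cubic polynomial of time, the detrend
#' applied to mean-intensity traces before sinewave fitting.
#'
#' @param trace numeric vector, at least 5 points.
#' @param times optional time vector (defaults to equally spaced).
#' @return detrended trace (residuals; mean 0).
#' @export
cubic_detrend <- function(trace, times = NULL) {
  n <- length(trace)
  if (n < 5L) stopf("cubic_detrend: need at least 5 points, got %d", n)
  if (is.null(times)) times <- seq_len(n)
  X <- cbind(1, stats::poly(times, 3, simple = TRUE))
  as.numeric(stats::lm.fit(X, trace)$residuals)
}

#' Tile a stack into fixed-lattice square ROIs and extract mean traces
#'
#' Non-overlapping `roi_size` x `roi_size` tiles on a lattice anchored
#' at the image origin (0, 0); trailing partial rows/columns are
#' dropped. Each retained ROI's trace is the per-frame mean over the
#' tile's in-mask pixels; tiles with less than `retention_frac` of
#' their pixels inside the tissue mask are dropped.
#'
#' @param stack a [frame_stack()] (typically moving-average detrended).
#' @param mask logical matrix, TRUE = tissue, same shape as frames.
#' @param roi_size tile side in pixels (default 3).
#' @param retention_frac minimum in-mask pixel fraction to retain a
#'   tile (default 0.5).
#' @return a `roi_series_set`: list with `series` (n_roi x n_frames
#'   matrix), `roi_centers` (0-based (row, col) of tile centers),
#'   `roi_id`, `mask_fraction`, `roi_size`, `frame_interval_h`, `t0_h`.
#' @export
tile_rois <- function(stack, mask, roi_size = 3L, retention_frac = 0.5) {
  shp <- frame_shape(stack)
  if (!identical(dim(mask), shp)) {
    stopf("tile_rois: mask shape %s does not match frames %s",
          paste(dim(mask), collapse = "x"), paste(shp, collapse = "x"))
  }
  mask <- mask != 0
  if (!any(mask)) stopf("tile_rois: empty mask")
  s <- as.integer(roi_size)
  n_tr <- shp[1] %/% s
  n_tc <- shp[2] %/% s
  nf <- n_frames(stack)
  fm <- matrix(stack$frames, nrow = nf)   # frames as n x (rows*cols), column-major

  rows_list <- list(); centers <- NULL; fracs <- numeric(0)
  for (tc in seq_len(n_tc)) {
    for (tr in seq_len(n_tr)) {
      rr <- ((tr - 1L) * s + 1L):(tr * s)
      cc <- ((tc - 1L) * s + 1L):(tc * s)
      sub <- mask[rr, cc]
      frac <- mean(sub)
      if (frac < retention_frac || !any(sub)) next
      # linear pixel indices of in-mask pixels of this tile
      pix <- outer(rr, (cc - 1L) * shp[1], `+`)[sub]
      tr_mean <- if (length(pix) == 1L) fm[, pix] else rowMeans(fm[, pix, drop = FALSE])
      rows_list[[length(rows_list) + 1L]] <- tr_mean
      centers <- rbind(centers, c((tr - 1L) * s + (s - 1L) / 2,
                                  (tc - 1L) * s + (s - 1L) / 2))
      fracs <- c(fracs, frac)
    }
  }
  if (!length(rows_list)) stopf("tile_rois: no tile meets retention_frac = %g", retention_frac)
  series <- do.call(rbind, rows_list)
  colnames(centers) <- c("row", "col")
  structure(list(series = series,
                 roi_centers = centers,
                 roi_id = seq_len(nrow(series)),
                 mask_fraction = fracs,
                 roi_size = s,
                 frame_interval_h = stack$frame_interval_h,
                 t0_h = stack$t0_h),
            class = "roi_series_set")
}

#' @export
print.roi_series_set <- function(x, ...) {
  cat(sprintf("<roi_series_set: %d ROIs (%dx%d px) x %d frames, dt = %g h>\n",
              nrow(x$series), x$roi_size, x$roi_size, ncol(x$series),
              x$frame_interval_h))
  invisible(x)
}

#' Mean intensity trace over a mask
#'
#' @param stack a [frame_stack()].
#' @param mask logical matrix (TRUE = include), same shape as frames.
#' @return numeric vector, one mean per frame.
#' @export
extract_mean_trace <- function(stack, mask) {
  shp <- frame_shape(stack)
  if (!identical(dim(mask), shp)) stopf("extract_mean_trace: mask shape mismatch")
  mask <- mask != 0
  if (!any(mask)) stopf("extract_mean_trace: empty mask")
  fm <- matrix(stack$frames, nrow = n_frames(stack))
  idx <- which(mask)
  if (length(idx) == 1L) fm[, idx] else rowMeans(fm[, idx, drop = FALSE])
}

#' Normalize timeseries for clustering or slope quantification
#'
#' `"zscore"` (default) rescales each series to mean 0, SD 1 — the
#' normalization used before K-means so clusters form by waveform
#' shape and phase rather than brightness. `"minmax"` maps the series
#' range to 0–100% — the normalization used for temperature-response
#' slope quantification.
#'
#' Constant series cannot be normalized; under z-score they are kept as
#' all zeros and flagged in the `"degenerate"` attribute.
#'
#' @param series numeric vector, or matrix with one series per row.
#' @param method "zscore" or "minmax".
#' @return normalized series, same shape, with a logical `"degenerate"`
#'   attribute (one flag per series).
#' @export
normalize_series <- function(series, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  vec <- !is.matrix(series)
  m <- if (vec) matrix(series, nrow = 1) else series
  degenerate <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (method == "zscore") {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        m[i, ] <- 0
        degenerate[i] <- TRUE
      } else {
        m[i, ] <- (x - mean(x)) / s
      }
    } else {
      r <- range(x)
      if (diff(r) == 0) {
        m[i, ] <- 0
        degenerate[i] <- TRUE
      } else {
        m[i, ] <- (x - r[1]) / diff(r) * 100
      }
    }
  }
  out <- if (vec) drop(m) else m
  attr(out, "degenerate") <- degenerate
  out
}
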