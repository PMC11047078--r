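# k-means++ initial centers (Arthur & Vassilvitskii seeding).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of normalized ROI timeseries
#'
#' Clusters z-scored ROI traces with the classical Lloyd (EM-style)
#' algorithm, k = 5 by default, seeded k-means++ initialization with
#' `n_init` restarts keeping the lowest within-cluster sum of squares.
#' Each cluster's mean timeseries is then fitted with
#' [fit_dominant_sinewave()]; clusters whose mean series fails the
#' rhythmicity criterion are labeled NR (nonrhythmic). Peak times use
#' `abs_phase_h`, controlling for period differences between clusters.
#'
#' @param rois a `roi_series_set` whose `series` are normalized
#'   (see [normalize_series()]).
#' @param k number of clusters (default 5).
#' @param seed integer seed governing initialization.
#' @param n_init number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart (default 300).
#' @param band_h,rae_threshold rhythm-fit settings for cluster mean
#'   series.
#' @return a `cluster_result`: `labels` (per ROI), `k`, `sizes`,
#'   `mean_series` (k x n_frames), `fits` (list of `rhythm_fit`),
#'   `is_nr` (per cluster), `com` (k x 2 center of mass of member ROI
#'   centers, pixels), `inertia`, `seed`, plus ROI bookkeeping.
#' @export
kmeans_timeseries <- function(rois, k = 5L, seed = 1L, n_init = 10L,
                              iter_max = 300L, band_h = c(16, 32),
                              rae_threshold = 0.3) {
  x <- rois$series
  n <- nrow(x)
  if (n < k) stopf("kmeans_timeseries: %d ROIs < k = %d", n, k)
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    warning(sprintf("kmeans_timeseries: only %d distinct series; reducing k from %d",
                    n_distinct, k))
    k <- n_distinct
  }

  best <- NULL
  with_seed(seed, {
    tries <- 0L
    done <- 0L
    while (done < n_init && tries < n_init * 4L) {
      tries <- tries + 1L
      init <- kmeanspp_init(x, k)
      km <- tryCatch(
        stats::kmeans(x, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          # "did not converge" warnings still return a usable fit
          tryCatch(suppressWarnings(
            stats::kmeans(x, centers = init, iter.max = iter_max,
                          algorithm = "Lloyd")), error = function(e) NULL)
        })
      if (is.null(km) || any(km$size == 0L)) next   # empty cluster: redraw
      done <- done + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stopf("kmeans_timeseries: no restart produced k nonempty clusters")

  labels <- best$cluster
  mean_series <- t(vapply(seq_len(k), function(j) {
    colMeans(x[labels == j, , drop = FALSE])
  }, numeric(ncol(x))))
  fits <- lapply(seq_len(k), function(j) {
    fit_dominant_sinewave(mean_series[j, ] - mean(mean_series[j, ]),
                          rois$frame_interval_h, band_h = band_h,
                          rae_threshold = rae_threshold)
  })
  is_nr <- !vapply(fits, function(f) isTRUE(f$is_rhythmic), logical(1))
  com <- t(vapply(seq_len(k), function(j) {
    colMeans(rois$roi_centers[labels == j, , drop = FALSE])
  }, numeric(2)))
  colnames(com) <- c("row", "col")

  structure(list(labels = labels, k = k, sizes = as.integer(best$size),
                 mean_series = mean_series, fits = fits, is_nr = is_nr,
                 com = com, inertia = best$tot.withinss, seed = seed,
                 roi_centers = rois$roi_centers, roi_id = rois$roi_id,
                 roi_size = rois$roi_size,
                 frame_interval_h = rois$frame_interval_h),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d, %d ROIs, inertia %.4g, %d NR cluster(s)>\n",
              x$k, length(x$labels), x$inertia, sum(x$is_nr)))
  invisible(x)
}

#' Per-pixel phase map of a cluster result
#'
#' Paints each retained ROI tile with its cluster's fitted peak time
#' (`abs_phase_h`). NR clusters are flagged in a separate logical
#' layer; pixels not covered by a retained ROI are NA.
#'
#' @param result a `cluster_result`.
#' @param shape (rows, cols) of the source image.
#' @return list with `phase` (numeric matrix, hours; NA off-ROI and on
#'   NR tiles) and `nr` (logical matrix, TRUE on NR-cluster tiles).
#' @export
cluster_phase_map <- function(result, shape) {
  s <- result$roi_size
  half <- (s - 1L) %/% 2L
  if (any(result$roi_centers[, 1] + half + 1L > shape[1]) ||
      any(result$roi_centers[, 2] + half + 1L > shape[2])) {
    stopf("cluster_phase_map: shape %s cannot contain the ROI lattice",
          paste(shape, collapse = "x"))
  }
  phase <- matrix(NA_real_, shape[1], shape[2])
  nr <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_along(result$labels)) {
    cl <- result$labels[i]
    r <- result$roi_centers[i, 1] - half + 1L   # back to 1-based tile rows
    c <- result$roi_centers[i, 2] - half + 1L
    rr <- r:(r + s - 1L); cc <- c:(c + s - 1L)
    if (result$is_nr[cl]) {
      nr[rr, cc] <- TRUE
    } else {
      phase[rr, cc] <- result$fits[[cl]]$abs_phase_h
    }
  }
  list(phase = phase, nr = nr)
}

#' Wave-direction vector from cluster centers of mass
#'
#' Orders rhythmic clusters by peak time (`abs_phase_h`), regresses the
#' center-of-mass column and row coordinates on the phase rank, and
#' reports the direction of spatial phase progression as
#' `atan2(row_slope, col_slope)` with the mean R-squared of the two
#' regressions. With fewer than two rhythmic clusters the vector is
#' flagged undefined rather than raising.
#'
#' @param result a `cluster_result`.
#' @param regressor "rank" (default; ordinal progression, insensitive
#'   to period effects) or "phase" (raw peak hours).
#' @return a `wave_vector`: `defined`, `angle_rad` in (-pi, pi],
#'   `r2`, `path` (ordered COMs), `n_clusters`.
#' @export
wave_vector <- function(result, regressor = c("rank", "phase")) {
  regressor <- match.arg(regressor)
  keep <- which(!result$is_nr)
  if (length(keep) < 2L) {
    return(structure(list(defined = FALSE, angle_rad = NA_real_, r2 = NA_real_,
                          path = NULL, n_clusters = length(keep)),
                     class = "wave_vector"))
  }
  ph <- vapply(result$fits[keep], `[[`, numeric(1), "abs_phase_h")
  # order by circular deviation from the mean phase: peak times that wrap
  # past the cycle boundary must not jump to the end of the ordering
  per <- mean(vapply(result$fits[keep], `[[`, numeric(1), "period_h"))
  ang <- 2 * pi * ph / per
  mu <- atan2(sum(sin(ang)), sum(cos(ang)))
  dev_h <- wrap_angle(ang - mu) * per / (2 * pi)
  ord <- order(dev_h)
  keep <- keep[ord]
  com <- result$com[keep, , drop = FALSE]
  xreg <- if (regressor == "rank") seq_along(keep) else dev_h[ord]
  fit_r <- stats::lm(com[, "row"] ~ xreg)
  fit_c <- stats::lm(com[, "col"] ~ xreg)
  slope_r <- stats::coef(fit_r)[[2]]
  slope_c <- stats::coef(fit_c)[[2]]
  # a coordinate with zero variance is fitted exactly by its mean line
  r2_of <- function(fit, yv) {
    tss <- sum((yv - mean(yv))^2)
    if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  }
  r2 <- mean(c(r2_of(fit_r, com[, "row"]), r2_of(fit_c, com[, "col"])))
  structure(list(defined = TRUE,
                 angle_rad = wrap_angle(atan2(slope_r, slope_c)),
                 r2 = r2, path = com, n_clusters = length(keep)),
            class = "wave_vector")
}

#' @export
print.wave_vector <- function(x, ...) {
  if (!x$defined) {
    cat("<wave_vector: undefined (<2 rhythmic clusters)>\n")
  } else {
    cat(sprintf("<wave_vector: angle %.1f deg, R2 = %.3f over %d clusters>\n",
                x$angle_rad * 180 / pi, x$r2, x$n_clusters))
  }
  invisible(x)
}
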