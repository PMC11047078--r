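# Shared fixture: 5 discrete planted phase bands across the tissue.
banded_result <- function(seed = 1, km_seed = 7, noise = "poisson", ...) {
  p <- synth_params(seed = seed, phase_span_h = 8, quantize_phase_bands = TRUE,
                    nonrhythmic_border_frac = 0, noise_model = noise,
                    gaussian_sd = 0, grid_shape = c(48, 48), n_frames = 240,
                    ...)
  g <- generate_stack(p)
  rois <- detrended_rois(g$stack, g$truth$tissue_mask)
  km <- kmeans_timeseries(rois, k = 5, seed = km_seed)
  list(km = km, rois = rois, truth = g$truth, stack = g$stack)
}

test_that("planted phase bands are recovered with high ARI and seeded determinism", {
  r <- banded_result()
  tl <- roi_truth_labels(r$rois, r$truth)
  keep <- !is.na(tl)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(r$km$labels[keep], tl[keep])
  expect_gte(ari, 0.9)

  r2 <- banded_result()
  expect_identical(r$km$labels, r2$km$labels)

  # label accounting: every ROI labelled once, sizes sum to ROI count
  expect_equal(sum(r$km$sizes), length(r$km$labels))
  expect_true(all(r$km$sizes >= 1))

  # cluster COM lies inside the bounding box of its members
  for (j in seq_len(r$km$k)) {
    mem <- r$km$roi_centers[r$km$labels == j, , drop = FALSE]
    expect_true(r$km$com[j, 1] >= min(mem[, 1]) && r$km$com[j, 1] <= max(mem[, 1]))
    expect_true(r$km$com[j, 2] >= min(mem[, 2]) && r$km$com[j, 2] <= max(mem[, 2]))
  }
})

test_that("clustering stability across different k-means seeds on well-separated bands", {
  skip_if_not_installed("mclust")
  r1 <- banded_result(km_seed = 7)
  r2 <- banded_result(km_seed = 99)
  expect_gte(mclust::adjustedRandIndex(r1$km$labels, r2$km$labels), 0.9)
})

test_that("derived cluster statistics are invariant to label permutation", {
  r <- banded_result()
  km <- r$km
  perm <- c(3L, 5L, 1L, 2L, 4L)
  km2 <- km
  km2$labels <- perm[km$labels]
  inv <- order(perm)
  km2$fits <- km$fits[inv]
  km2$is_nr <- km$is_nr[inv]
  km2$com <- km$com[inv, ]
  km2$sizes <- km$sizes[inv]
  km2$mean_series <- km$mean_series[inv, ]

  s1 <- cluster_circular_stats(km)
  s2 <- cluster_circular_stats(km2)
  expect_equal(s1, s2, tolerance = 1e-12)
  w1 <- wave_vector(km)
  w2 <- wave_vector(km2)
  expect_equal(w1$angle_rad, w2$angle_rad, tolerance = 1e-12)
  expect_equal(w1$r2, w2$r2, tolerance = 1e-12)
})

test_that("identical series reduce k with a warning; too few ROIs error", {
  rois <- list(series = matrix(rep(c(1, -1), each = 50), nrow = 10, ncol = 100,
                               byrow = TRUE),
               roi_centers = cbind(row = seq(1, 28, 3), col = seq(1, 28, 3)),
               roi_id = 1:10, roi_size = 3L, frame_interval_h = 1)
  class(rois) <- "roi_series_set"
  expect_warning(km <- kmeans_timeseries(rois, k = 5, seed = 1), "reducing k")
  expect_equal(km$k, 1L)
  expect_error(kmeans_timeseries(rois, k = 50, seed = 1), "< k")
})

test_that("the wave vector recovers planted propagation directions", {
  for (ang_deg in c(0, 45, 90)) {
    p <- quiet_params(grid_shape = c(48, 48), n_frames = 240,
                      wave_angle_rad = ang_deg * pi / 180, phase_span_h = 8,
                      quantize_phase_bands = TRUE, seed = 2)
    g <- generate_stack(p)
    rois <- detrended_rois(g$stack, g$truth$tissue_mask)
    km <- kmeans_timeseries(rois, k = 5, seed = 7)
    wv <- wave_vector(km)
    expect_true(wv$defined)
    err <- abs((wv$angle_rad * 180 / pi - ang_deg + 180) %% 360 - 180)
    expect_lt(err, 10)
  }
})

test_that("rotating the stack by 90 degrees rotates the recovered wave angle by 90", {
  p <- quiet_params(grid_shape = c(48, 48), n_frames = 240, wave_angle_rad = 0,
                    phase_span_h = 8, quantize_phase_bands = TRUE, seed = 2)
  g <- generate_stack(p)
  analyse <- function(stack, mask) {
    rois <- detrended_rois(stack, mask)
    wave_vector(kmeans_timeseries(rois, k = 5, seed = 7))
  }
  wv0 <- analyse(g$stack, g$truth$tissue_mask)

  # rotate frames and mask 90 degrees clockwise: new[r, c] = old[n - c + 1, r]
  nr <- dim(g$stack$frames)[2]
  rot <- g$stack
  rot$frames <- aperm(g$stack$frames, c(1, 3, 2))[, , nr:1]
  mask_rot <- t(g$truth$tissue_mask)[, nr:1, drop = FALSE]
  wv90 <- analyse(rot, mask_rot)
  diff_deg <- abs(((wv90$angle_rad - wv0$angle_rad) * 180 / pi) %% 360 - 90)
  expect_lt(min(diff_deg, abs(diff_deg - 180)), 10)
})

test_that("two rhythmic clusters give an exact line through their COMs", {
  km <- structure(list(
    labels = c(1L, 1L, 2L, 2L), k = 2L, sizes = c(2L, 2L),
    fits = list(fake_fit(24, abs_phase_h = 3), fake_fit(24, abs_phase_h = 9)),
    is_nr = c(FALSE, FALSE),
    com = rbind(c(10, 4), c(20, 16)),
    roi_centers = rbind(c(10, 4), c(10, 4), c(20, 16), c(20, 16)),
    roi_size = 3L, frame_interval_h = 0.5), class = "cluster_result")
  colnames(km$com) <- c("row", "col")
  wv <- wave_vector(km)
  expect_true(wv$defined)
  expect_equal(wv$r2, 1)
  expect_equal(wv$angle_rad, atan2(10, 12), tolerance = 1e-12)

  km$is_nr <- c(FALSE, TRUE)
  wv_un <- wave_vector(km)
  expect_false(wv_un$defined)
  expect_true(is.na(wv_un$angle_rad))
})

test_that("phase maps paint tiles with cluster peak times and flag NR clusters", {
  r <- banded_result()
  pm <- cluster_phase_map(r$km, dim(r$stack$frames)[2:3])
  expect_equal(dim(pm$phase), c(48, 48))
  # painted phases are exactly the cluster abs peak times
  vals <- sort(unique(pm$phase[!is.na(pm$phase)]))
  fits_ph <- sort(vapply(r$km$fits[!r$km$is_nr], `[[`, numeric(1), "abs_phase_h"))
  expect_equal(vals, fits_ph, tolerance = 1e-9)
  # phase increases along the planted wave axis (columns)
  colmeans <- tapply(pm$phase[!is.na(pm$phase)], col(pm$phase)[!is.na(pm$phase)],
                     mean)
  expect_gt(cor(as.numeric(names(colmeans)), colmeans, method = "spearman"), 0.9)

  # all-NR input paints no phases
  km_nr <- r$km
  km_nr$is_nr <- rep(TRUE, km_nr$k)
  pm_nr <- cluster_phase_map(km_nr, c(48, 48))
  expect_true(all(is.na(pm_nr$phase)))
  expect_true(any(pm_nr$nr))
  expect_error(cluster_phase_map(r$km, c(10, 10)), "shape")
})
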