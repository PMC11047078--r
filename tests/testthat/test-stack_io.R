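test_that("read_stack demands a sidecar frame interval and homogeneous pages", {
  dir <- withr::local_tempdir()
  hetero <- file.path(dir, "hetero.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.1, 4, 4)), hetero,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(frame_interval_h = 1), paste0(hetero, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_stack(hetero), "page 2")

  ok <- file.path(dir, "ok.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), ok,
                  bits.per.sample = 16L)
  expect_error(read_stack(ok), "sidecar")
  jsonlite::write_json(list(channel = "x"), paste0(ok, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_stack(ok), "frame_interval_h")

  # sidecar without temperature_epochs loads; schedule-dependent ops refuse
  jsonlite::write_json(list(frame_interval_h = 1, channel = "x"),
                       paste0(ok, ".json"), auto_unbox = TRUE)
  st <- read_stack(ok)
  expect_null(st$schedule)
  expect_error(epoch_slopes(rnorm(10) + 10, 1, st$schedule), "schedule")
})

test_that("moving-average detrend removes slow trends but keeps the oscillation", {
  t <- seq(0, 119.5, by = 0.5)
  slope_in <- 2
  y <- 50 * cos(2 * pi * t / 24) + slope_in * t + 300
  det <- moving_average_detrend(y, window_h = 24.5, frame_interval_h = 0.5)
  # residual linear trend < 1% of the input slope (least-squares oracle)
  slope_out <- coef(lm(det ~ t))[[2]]
  expect_lt(abs(slope_out), 0.01 * slope_in)
  # oscillation survives: amplitude of detrended interior close to planted
  expect_gt(diff(range(det[30:210])), 90)

  expect_error(moving_average_detrend(y, window_h = 125, frame_interval_h = 0.5),
               "longer than the recording")
})

test_that("moving-average detrend maps constants to zero and is linear", {
  st <- flat_stack(value = 7)
  det <- moving_average_detrend(st, window_h = 5)
  expect_lt(max(abs(det$frames)), 1e-12)

  m <- matrix(rnorm(200 * 3), 200, 3)
  a <- 2.5; b <- 40
  d1 <- moving_average_detrend(a * m + b, window_h = 24.5, frame_interval_h = 0.5)
  d2 <- a * moving_average_detrend(m, window_h = 24.5, frame_interval_h = 0.5)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("cubic detrend removes exact cubics, keeps dominant period, needs 5 points", {
  t <- seq(0, 119.5, by = 0.5)
  cubic <- 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3
  expect_lt(max(abs(cubic_detrend(cubic, times = t))), 1e-8)

  y <- 20 * cos(2 * pi * (t - 6) / 23.3)
  f_raw <- fit_dominant_sinewave(y - mean(y), 0.5)
  f_det <- fit_dominant_sinewave(cubic_detrend(y, times = t), 0.5)
  expect_equal(f_det$period_h, f_raw$period_h, tolerance = 0.05)
  expect_lt(abs(mean(cubic_detrend(y, times = t))), 1e-9)

  expect_error(cubic_detrend(c(1, 2, 3, 4)), "5 points")
})

test_that("ROI tiling follows the fixed lattice with floor division and retention rule", {
  st <- flat_stack(value = 3, nr = 64, nc = 64)
  full <- matrix(TRUE, 64, 64)
  rois <- tile_rois(st, full, roi_size = 3)
  expect_equal(nrow(rois$series), 441)      # 21 x 21 complete tiles
  expect_equal(nrow(unique(rois$roi_centers)), 441)
  # centers sit on the 3-px lattice (0-based tile centers 1, 4, 7, ...)
  expect_true(all((rois$roi_centers[, 1] - 1) %% 3 == 0))
  expect_true(all(rois$mask_fraction == 1))

  # one-tile mask: single ROI whose trace is the 9-pixel mean
  st2 <- flat_stack(value = 0, nr = 12, nc = 12, nf = 4)
  vals <- matrix(seq_len(144), 12, 12)
  for (i in 1:4) st2$frames[i, , ] <- vals * i
  mask1 <- matrix(FALSE, 12, 12); mask1[4:6, 7:9] <- TRUE
  r1 <- tile_rois(st2, mask1, roi_size = 3)
  expect_equal(nrow(r1$series), 1)
  expect_equal(r1$series[1, ], mean(vals[4:6, 7:9]) * (1:4))
  expect_equal(unname(r1$roi_centers[1, ]), c(4, 7))   # 0-based center

  expect_error(tile_rois(st2, matrix(FALSE, 12, 12)), "empty mask")
  expect_error(tile_rois(st2, matrix(TRUE, 10, 10)), "shape")

  # tiles straddling the mask edge are dropped below the retention fraction
  mask_part <- matrix(FALSE, 12, 12); mask_part[1:12, 1:4] <- TRUE
  rp <- tile_rois(st2, mask_part, roi_size = 3, retention_frac = 0.5)
  expect_true(all(rp$mask_fraction >= 0.5))
  # second tile column has 1/3 of pixels in-mask: dropped
  expect_true(all(rp$roi_centers[, 2] == 1))
})

test_that("mean trace extraction averages in-mask pixels only", {
  st <- flat_stack(value = 4, nr = 8, nc = 8, nf = 6)
  mask <- matrix(TRUE, 8, 8)
  expect_equal(extract_mean_trace(st, mask), rep(4, 6))

  st$frames[, 3, 5] <- 1:6
  single <- matrix(FALSE, 8, 8); single[3, 5] <- TRUE
  expect_equal(extract_mean_trace(st, single), 1:6)
  expect_error(extract_mean_trace(st, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("series normalization: z-score, min-max, and degenerate flagging", {
  expect_equal(as.numeric(normalize_series(c(0, 10), method = "minmax")),
               c(0, 100))
  x <- matrix(rnorm(5 * 50, mean = 3, sd = 7), 5, 50)
  z <- normalize_series(x)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
  expect_false(any(attr(z, "degenerate")))

  m <- rbind(rep(2, 10), rnorm(10))
  zm <- normalize_series(m)
  expect_identical(attr(zm, "degenerate"), c(TRUE, FALSE))
  expect_true(all(zm[1, ] == 0))
})

test_that("every in-mask pixel belongs to at most one retained ROI", {
  p <- quiet_params(grid_shape = c(32, 32), n_frames = 160, seed = 2)
  g <- generate_stack(p)
  rois <- tile_rois(g$stack, g$truth$tissue_mask)
  s <- rois$roi_size
  covered <- matrix(0L, 32, 32)
  for (i in seq_len(nrow(rois$roi_centers))) {
    rr <- rois$roi_centers[i, 1] + (0:2)   # 0-based center - 1 + 1-based shift
    cc <- rois$roi_centers[i, 2] + (0:2)
    covered[rr, cc] <- covered[rr, cc] + 1L
  }
  expect_true(all(covered <= 1L))
})
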