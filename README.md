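# scnwave

Spatiotemporal analysis of circadian reporter image timeseries in SCN
explants.

Organotypic slices of the suprachiasmatic nucleus (SCN) sustain
autonomous ~24 h rhythms that can be imaged for weeks with
bioluminescent clock reporters (PER2::LUC), transcriptional reporters
of clock-controlled genes (Rbm3-Luc, cold-inducible), and calcium
indicators (jRCaMP1a). Experiments that step the chamber temperature
(37 °C ↔ 32 °C) ask whether downstream clock-controlled pathways stay
temperature-compensated the way the core clock does, and whether the
tissue's spatiotemporal wave organization survives thermal challenge.
`scnwave` is the analysis side of such experiments, for researchers
who have multi-day TIFF stacks and need per-slice quantitative
readouts.

## What it computes

* **Rhythm estimation** — the dominant circadian sinewave
  `y(t) = A·cos(2π(t − φ)/τ) + c` of a detrended trace, seeded by a
  zero-padded FFT periodogram and refined by Levenberg–Marquardt least
  squares; period, amplitude, peak phase in both the absolute
  ("first peak after window start") and 24 h circadian conventions,
  goodness of fit, and a rhythmicity call via the relative amplitude
  error (RAE = amplitude CI half-width / amplitude, rhythmic iff
  RAE ≤ 0.3 within the 16–32 h search band).
* **Detrending and ROI extraction** — cubic detrend for mean-intensity
  traces; centered 24.5 h moving-average detrend for image series;
  tiling into 3×3-pixel ROIs with per-ROI normalized traces.
* **Spatiotemporal clustering** — Lloyd K-means (k = 5, seeded
  k-means++ with restarts) of z-scored ROI traces, per-cluster rhythm
  fits with cluster-level NR labels, phase maps, and wave-direction
  vectors from linear regression of cluster centers of mass on phase
  rank.
* **Circular statistics** — circular mean/SD and the circular variance
  `1 − √((Σ sin x)² + (Σ cos x)²)/n` of cluster phases or vector
  angles; mean and SD of cluster periods.
* **Temperature response** — per-epoch slopes of min-max (0–100 %)
  normalized expression, Δperiod per epoch relative to the recording
  mean, relative amplitude (post/pre), and cross-reporter slope
  regression (R², F-test p) across slices.
* **Synthetic ground truth** — a generator of SCN-like single- or
  dual-reporter stacks (elliptical tissue, phase wave, per-epoch
  temperature effects, photon noise, nonrhythmic border, configurable
  reporter lag) so every stage is testable by parameter recovery.

## Worked example

Simulate a 10-day dual-epoch recording (37 °C then 32 °C, planted
period 23.3 h lengthening by 1 h in the cold, cold-induced expression
slope) and analyse it:

```r
library(scnwave)

sch <- temperature_schedule(c(0, 120), c(120, 240), c(37, 32))
p <- synth_params(grid_shape = c(48, 48), n_frames = 240, frame_interval_h = 1,
                  baseline_period_h = 23.3, period_shift_per_epoch_h = c(0, 1),
                  baseline_slope_per_epoch = c(-0.3, 0.8), phase_span_h = 8,
                  temperature_schedule = sch, seed = 42)
g <- generate_stack(p)

tr <- extract_mean_trace(g$stack, g$truth$tissue_mask)
fit_dominant_sinewave(cubic_detrend(tr), 1)
#> <rhythm_fit: period 23.83 h, amplitude 379, peak at 2.70 h (CT 2.71), RAE 0.050, GOF 0.869>

rois <- tile_rois(moving_average_detrend(g$stack), g$truth$tissue_mask)
rois$series <- normalize_series(rois$series)
km <- kmeans_timeseries(rois, k = 5, seed = 7)
km
#> <cluster_result: k = 5, 148 ROIs, inertia 565.9, 0 NR cluster(s)>
wave_vector(km)
#> <wave_vector: angle 0.0 deg, R2 = 0.996 over 5 clusters>
cluster_circular_stats(km)
#>   intercluster_circvar period_mean_h period_sd_h n_rhythmic_clusters
#> 1            0.1733901      23.82633    0.032134                   5

epoch_slopes(tr, 1, sch)
#>   epoch temp_c slope_pct_per_h intercept_pct        r2 n_frames_used
#> 1     1     37      -0.2235426      39.41394 0.2237962           120
#> 2     2     32       0.4420991     -36.67889 0.3763840           120
delta_period(fit_per_epoch(tr, 1, sch))
#>   epoch temp_c period_h delta_period_h
#> 1     1     37 23.31308     -0.5002977
#> 2     2     32 24.31368      0.5002977
```

Reading the output: the whole-recording fit lands between the two
planted epoch periods (23.83 h, a mixture of 23.3 and 24.3); the wave
vector recovers the planted left-to-right phase progression (0°) with
the five clusters' peak phases spanning the 8 h planted lag
(intercluster circular variance 0.17); the negative/positive epoch
slopes recover the planted reporter decay at 37 °C and cold induction
at 32 °C; and Δperiod shows the planted 1 h cooling-induced
lengthening split symmetrically around the recording-mean period.

The full pipeline — simulate (or read TIFF + JSON sidecar), detrend,
tile, cluster, statistics, temperature response, provenance — runs as

```r
run_pipeline(pipeline_config(synth = list(seed = 1)), "runs/r1")
```

or from a shell via `inst/exec/scnwave all --config cfg.yaml --out runs/r1`.

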