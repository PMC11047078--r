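---
title: "Methods: spatiotemporal analysis of circadian reporter image timeseries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of circadian reporter image timeseries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnwave)
```

## Scope

`scnwave` analyses multi-day image timeseries of circadian reporters in
SCN explants — bioluminescent clock reporters such as PER2::LUC, a
cold-inducible transcriptional reporter such as Rbm3-Luc, and calcium
indicators such as jRCaMP1a — recorded while the chamber temperature is
stepped between levels (typically 37 °C and 32 °C). It quantifies
(i) the dominant circadian sinewave of a trace (period, amplitude, peak
phase, rhythmicity), (ii) the spatiotemporal organization of the tissue
(K-means clusters of ROI traces, per-cluster peak phases, intercluster
circular variance, wave-direction vectors), and (iii) temperature-evoked
changes (per-epoch expression slopes, period changes, relative
amplitude, cross-reporter slope regression). A synthetic stack generator
with fully known ground truth underpins all validation.

Out of scope by design: motion correction, background/flat-field
correction, cell segmentation, and all group-level hypothesis testing
(the package emits per-slice metrics; group inference belongs in
standard statistical tools).

## The rhythm model

A detrended trace is modelled as a single undamped cosine plus offset,

$$y(t) = A \cos\!\big(2\pi (t - \varphi)/\tau\big) + c,$$

fitted in two stages: a zero-padded FFT periodogram proposes the
highest-power period inside a circadian search band (default 16–32 h,
wide enough for Cry-mutant short periods and cooling-lengthened
periods), then Levenberg–Marquardt least squares refines
$(A, \varphi, \tau, c)$ with an analytic Jacobian. Damping and
multi-component structure are deliberately absent: the slow envelope is
removed by detrending, and the readouts of interest are the period,
amplitude and peak phase of the dominant component only.

Phase is reported in two conventions. `abs_phase_h` is the first peak
of the fitted cosine after the analysis-window start ("absolute phase
to zero"); it is the peak-time used for cluster comparisons because it
is insensitive to period differences between clusters. `circ_phase_h`
maps that peak onto a common 24-h circadian scale,
$\mathrm{abs} \times 24/\tau \bmod 24$.

Rhythmicity is classified by the relative amplitude error,
$\mathrm{RAE} = t_{0.975,\,n-4}\,\mathrm{SE}(A)/A$ with
$\mathrm{SE}(A)$ from the linearized covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the solution. A trace is rhythmic iff
RAE ≤ 0.3 and the fitted period lies inside the search band. The 0.3
default is a conventional imaging-rhythmicity cut-off; no printed
criterion exists for these data, so the threshold is exposed in the
configuration and recorded in output provenance. A flat spectrum,
constant trace or solver failure yields a nonrhythmic result with a
diagnostic flag rather than an error.

### Detrending

Two detrends serve different purposes:

* `cubic_detrend()` (least-squares cubic of time) precedes whole-trace
  and per-epoch sinewave fits of mean-intensity traces.
* `moving_average_detrend()` (centered running mean, window 24.5 h,
  window length in frames rounded and forced odd, shrinking
  symmetrically at the recording edges rather than padding) precedes
  ROI-grid extraction for clustering. Just over one cycle long, the
  window tracks baseline drift while averaging the oscillation out.

A property worth knowing: subtracting a cubic fitted over a finite
window perturbs a pure cosine in a phase-dependent way, biasing fitted
periods and peak times by amounts that shrink roughly quadratically
with the number of recorded cycles (about 0.3 h in peak time at 5
cycles, under 0.1 h at 10). Peak-phase comparisons between reporters
are therefore made on recordings of ten days in the validation suite,
matching the multi-week recordings this kind of experiment actually
produces. Likewise, an ordinary least-squares line fitted across $n$
whole cycles of a cosine of amplitude $A$ retains slope
$12 A \sin\varphi_0 / (\omega L^2)$ — rhythm leakage that only
vanishes relative to a trend when the trend dominates the oscillation,
which is the regime the temperature-step slope readout is designed for
(cold induction in these recordings dwarfs the circadian modulation).

## ROI grid and normalization

The tissue is tiled with non-overlapping 3×3-pixel ROIs on a fixed
lattice anchored at the image origin; trailing partial rows/columns are
dropped (a 64×64 frame yields 21×21 = 441 tiles). Each ROI's trace is
the per-frame mean over the tile's in-mask pixels; tiles with less than
half their pixels in the mask are dropped. The fixed anchor makes
cluster maps reproducible; the 0.5 retention default is an edge rule
the protocol leaves open.

Before clustering, each ROI trace is z-scored. Z-scoring (rather than
min-max) makes K-means group by waveform shape and phase rather than
brightness; min-max scaling to 0–100 % is reserved for the
temperature-response slope quantification, where comparability in
percent of dynamic range is the point. Constant series cannot be
normalized; they are kept as zeros and flagged.

## Clustering and wave vectors

`kmeans_timeseries()` runs the classical Lloyd algorithm with k = 5 on
the z-scored traces, with seeded k-means++ initialization and 10
restarts keeping the lowest within-cluster sum of squares
(initialization is not specified by the protocol; restarts guard
against poor local minima, and the seed is recorded). A restart that
produces an empty cluster is discarded and redrawn. If the input
contains fewer distinct series than k, k is reduced with a warning.

Each cluster's mean trace is fitted with the rhythm model;
nonrhythmic clusters are labelled NR at the cluster level (matching the
cluster-level NR labels of the phase maps), and `abs_phase_h` of the
mean-series fit is the cluster peak time. The wave-direction vector
orders rhythmic clusters by peak time — circularly, as signed deviation
from the circular mean phase, so a cluster whose peak wraps just past
the cycle boundary sorts first rather than last — then regresses the
center-of-mass row
and column coordinates on the phase *rank*, and reports
$\mathrm{atan2}(\beta_{row}, \beta_{col})$ with the mean $R^2$ of the
two regressions. Rank (ordinal progression) rather than raw phase is
the default regressor — consistent with using period-insensitive peak
times — with raw phase available as an option. With fewer than two
rhythmic clusters the vector is flagged undefined.

## Circular statistics

Cluster peak phases (hours) are mapped to angles by
$x = 2\pi \cdot \mathrm{phase}/24$ on a common 24-h circle — chosen
over per-cluster period circles so that intercluster comparisons share
one scale. The dispersal statistic is the circular variance

$$\mathrm{Circvar} = 1 - \frac{\sqrt{(\sum \sin x)^2 + (\sum \cos x)^2}}{n},$$

0 for perfectly clustered phases and exactly 1 for evenly dispersed
ones. The circular mean is $\mathrm{atan2}(\sum\sin x, \sum\cos x)$
with circular SD $\sqrt{-2\ln \bar R}$; it is flagged undefined when
the resultant length vanishes (e.g. an antipodal pair). Period
dispersion across clusters uses the arithmetic mean and the sample SD
(n − 1 denominator) of rhythmic clusters' periods.

## Temperature response

For expression slopes the raw trace is min-max normalized over the
full recording (largest value 100 %, smallest 0 % — full-recording
rather than per-epoch so slopes are comparable across epochs), then an
OLS line is fitted independently within each temperature epoch; the
slope in %/h summarizes the temperature-evoked change in reporter
dynamics. Per-epoch rhythm fits skip the first 12 h after each
temperature step (the acute transient) and require at least two full
cycles of the upper band period afterwards; shorter epochs are flagged
rather than fitted. Δperiod is each rhythmic epoch's period minus the
unweighted mean over rhythmic epochs (summing to zero by
construction); relative amplitude is the post/pre ratio of fitted
amplitudes; cross-reporter coupling is the per-epoch OLS of one
reporter's slice slopes on the other's, with $R^2$ and the regression
F-test p-value, reported per epoch without multiplicity correction
(a Bonferroni option exists in configuration).

## The synthetic generator

`generate_stack()` emulates a single-nucleus SCN recording: an
elliptical tissue mask (semi-axes 0.42 of the grid); per-pixel
intensity

$$I(t) = \mathrm{yield}_e \cdot B_e(t)\,\big[1 + a_e
  \cos(\Theta(t) - 2\pi\phi_{px}/\tau_1)\big]$$

with a piecewise-linear baseline $B_e(t)$ (slopes in % of the baseline
level per hour, changing at temperature steps), per-epoch period
$\tau_e$ with continuously accumulated phase $\Theta(t)$, per-epoch
amplitude scale, and an optional per-epoch photon-yield factor (since
luciferase photon emission itself drops with temperature, the
analysis's robustness to that artifact can be probed). The planted
phase $\phi_{px}$ is a linear ramp along a configurable wave angle
(the dorsomedial-to-ventrolateral wave analogue), spanning
`phase_span_h` hours; the outermost rim of tissue pixels can be made
nonrhythmic. Noise is Poisson on expected counts (bioluminescence) or
Gaussian (fluorescence); outside-mask pixels carry background noise
only. A second reporter shares the geometry with its phases shifted by
`reporter_lag_h` (default 4 h, the luciferase-after-calcium lag) and
draws independent noise. One seeded generator drives each call; the
seed is recorded in the ground truth.

Cluster ground truth is the assignment of pixels to `n_phase_bands`
equal-count bands of the planted phase. Because a continuous ramp has
no unambiguous 5-cluster structure (any segmentation of a continuum is
partly arbitrary; K-means recovers quantile bands of an elliptical
tissue only to ARI ≈ 0.87 even without noise), the generator offers
`quantize_phase_bands = TRUE`, which snaps each band's pixels to the
band-mean phase. That plants five discrete phase groups — the
configuration used for clustering-recovery validation — while the
continuous ramp remains the default for wave-direction work.

Defaults mirror the study conditions: 64×64 px, 240 frames at 0.5 h
(five days at the movie cadence; the montage interval of 3 h is far
coarser than the recording cadence, so 0.5 h is the generator default
and configurable), period 24 h (23.3 h planted when mirroring the
measured free-running periods), amplitude 0.5 of baseline, 1000
counts/frame, phase span 8 h, 5 % nonrhythmic border.

## What the validation does and does not show

All validation is parameter recovery on synthetic stacks, because the
original recordings are not deposited. Passing tests show the
estimators are unbiased and precise under the generator's assumptions:
a clean multiplicative cosine with piecewise-constant temperature
effects, an exact elliptical mask, no drift in space, Poisson/Gaussian
noise. Real recordings add phenomena the generator deliberately omits
— damped amplitudes, waveform asymmetry, tissue motion, flat-field
structure, optical crosstalk between reporters — so the tests validate
the computation, not the biology. Problem sizes in the test-suite are
chosen to exercise every code path at desk scale: grids of 16–64 px,
recordings of 5–12 days, 10–50 replicate simulations per stochastic
claim.

Known numerical choices and degenerate-input behaviour, in brief:
FFT periodograms are zero-padded to at least 8× the trace length;
solver failures and flat spectra yield NR flags, never exceptions;
negative fitted amplitudes are folded into the phase by a half-period
shift; empty masks, heterogeneous TIFF pages, missing sidecar frame
intervals, constant traces for slope fitting, and schedules that do not
span the recording all fail loudly with named causes; the realized
nonrhythmic border fraction on small grids deviates from the requested
one because pixel radii tie on symmetric grids.

## Known limitations

* The sinewave model is single-component and undamped; strongly damped
  or multi-peaked rhythms are summarized only by their dominant
  component.
* Sequential detrend-then-fit carries small finite-window biases
  (quantified above); they are negligible for ≥10-day windows but can
  reach ~0.05 h in period and ~0.3 h in peak time at 5 days.
* The wave vector is a single global direction; curved or converging
  waves are reduced to their principal progression.
* NR classification happens at cluster level, so a rhythmic minority
  inside a nonrhythmic cluster is not recovered.
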