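# saltatrack

Analysis of saltatory organelle transport in time-lapse fluorescence
microscopy, built around the peroxisome-trafficking assay used to study
SPAST-mutated cells from patients with hereditary spastic paraplegia.
Peroxisomes in thin, actin-free "axon-like" processes move in stop-and-go
(saltatory) fashion along microtubules: a minority (~10% in healthy
controls) shows fast directed transport, the rest drift slowly or sit
still. Disease shifts the *numbers* — fewer fast movers, fewer retrograde
movers, a left-shifted speed distribution — while leaving the saltatory
*dynamics* of individual moving organelles intact. `saltatrack` provides
every quantitative step of that analysis, plus a ground-truth simulator so
each step is testable without any microscope.

## What it implements

* **Synthetic data** — three-class motion model (fast run-and-pause with
  per-organelle direction, heterogeneous Brownian-like slow motion,
  immobile) on a quasi-1D process; movie rendering with Gaussian PSF,
  Poisson shot noise and read noise; multi-channel cell fields for
  fluorescence quantification. Presets: `control`, `patient`,
  `patient_epoD` (epothilone-D rescue).
* **Detection** — maximum-intensity projection, Laplacian-of-Gaussian blob
  filtering matched to the expected spot diameter, robust auto-threshold,
  subpixel centroids.
* **Tracking** — exact optimal-assignment frame-to-frame linking
  (Hungarian algorithm with birth/death slots) and the completeness filter
  (tracks not observed in every frame are deleted).
* **Motion metrics** — instantaneous and mean speeds, saltatory-event
  segmentation (speeds strictly above 0.1 μm/s), fast-mover classification
  (mean speed strictly above 0.14 μm/s, the control 90th percentile),
  anterograde/retrograde calls, density windows along the process.
* **Population statistics** — check-loss quantiles and per-quantile group
  contrasts with bootstrap inference, unpaired t tests from raw values or
  printed mean ± SEM summaries, Pearson chi-square, mixed repeated-measures
  ANOVA (between: disease status; within: treatment), per-line fast-mover
  percentages.
* **Cell fluorescence** — nucleus segmentation, seeded cytoplasm
  partition ("between the nucleus and the cell edge"), per-cell marker
  means for oxidative-stress readouts such as 4HNE.

## Worked example

Simulate a small control and patient experiment, push both through the
full imaging pipeline (render → detect → link → filter → summarise), and
compare the groups:

```r
library(saltatrack)

im   <- imaging_params(pixel_size = 0.25, n_z = 1)
ctrl <- simulate_and_recover("control", n_lines = 2, tracks_per_line = 60,
                             seed = 42, imaging = im)
pat  <- simulate_and_recover("patient", n_lines = 2, tracks_per_line = 60,
                             seed = 43, imaging = im)
st <- group_statistics(ctrl$summaries, pat$summaries, seed = 1)

st$fast$control$overall_pct    # 10
st$fast$patient$overall_pct    # 3.3
st$percentiles
#    tau control patient
# 1 0.10  0.0195  0.0196
# 2 0.25  0.0213  0.0214
# 3 0.50  0.0386  0.0397
# 4 0.75  0.0585  0.0546
# 5 0.90  0.1419  0.0753
st$t_mean_speed
# t/statistic = 18.06, df = 2, p = 0.003051
# estimate = 0.01149 +/- 0.0006363 (95% CI 0.008756 to 0.01423)
```

Reading it: 10% of recovered control tracks but only 3.3% of patient
tracks exceed the 0.14 μm/s fast-mover threshold; the control 90th
percentile sits at that threshold (0.142 μm/s) while the patient
distribution is shifted left (0.075 μm/s); and the line-level t test
shows the patient mean speed deficit. At this demo size (120 tracks per
group, 2 lines) the confidence intervals are wide — the test suite and
acceptance script run larger designs.

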