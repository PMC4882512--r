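---
title: "Saltatory transport analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saltatory transport analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltatrack)
```

# The problem

Peroxisomes are carried along axonal microtubules by motor proteins in
*saltatory* fashion: bursts of directed transport separated by pauses. In
cells from patients with SPAST-mutated hereditary spastic paraplegia the
pool of stable microtubules is reduced, and time-lapse imaging of
GFP-labelled peroxisomes in actin-free, axon-like processes shows fewer
peroxisomes travelling fast, a leftward shift of the whole speed
distribution, and a loss of retrograde transport — while the saltatory
dynamics of the peroxisomes that do move remain normal. `saltatrack`
implements the quantitative chain behind such observations as reusable,
tested components:

1. a generative model of three-class organelle motion along a quasi-1D
   process, with movie rendering, so every downstream stage can be
   validated against known ground truth;
2. spot detection on maximum-intensity projections and frame-to-frame
   track linking;
3. per-track saltatory metrics (mean speed, event segmentation,
   fast-mover and direction classification, density windows);
4. the population statistics used to compare patient and control groups
   (quantile contrasts, summary t tests, chi-square tables, mixed
   repeated-measures ANOVA);
5. per-cell cytoplasmic fluorescence quantification for oxidative-stress
   markers such as 4HNE.

# The motion model

Each organelle belongs to one of three classes:

* **fast** — alternates runs and pauses. Run and pause durations are
  exponential with means `fast_run_duration_mean` (default 5 s) and
  `fast_pause_duration_mean` (7 s); each run's speed is drawn from a
  normal truncated at zero (`fast_run_speed_mean` 0.52 μm/s, SD 0.25) and
  the direction — anterograde with probability `p_anterograde` — is drawn
  **once per organelle**, so its net displacement reflects the directional
  class the way per-organelle visual scoring does. (Independent per-run
  directions would make the sign of the net displacement of a
  many-run track concentrate far above `p_anterograde`, contradicting the
  per-organelle anterograde/retrograde fractions the model is meant to
  reproduce.)
* **slow** — a Brownian-like walk with zero-mean normal per-frame steps.
  The step SD is itself heterogeneous between organelles:
  `slow_step_sd * exp(N(0, slow_step_sd_spread))` with median 0.1 μm/frame
  and `sdlog` 0.45. Without this heterogeneity the per-track mean-speed
  distribution is a set of narrow class-wise spikes and the population
  90th percentile falls into the empty gap between classes; with it the
  distribution is continuous, as in real populations. Setting the spread
  to 0 recovers identical slow organelles.
* **immobile** — localization noise only (`loc_noise_sd`, 0.02 μm per
  coordinate).

Condition presets fix the published population structure: controls have
10% fast movers with 60.9% of them anterograde; patient cells 2.3% fast
with 86.1% anterograde; the epothilone-D preset models the
microtubule-stabilising rescue by restoring the control fast fraction
while keeping the patient directional bias. The non-fast mass is split
70/30 between slow and immobile in all presets — a free parameter the
source data do not constrain per condition.

## Calibration of the free speed parameters

The run/pause/speed defaults are a calibration, not published facts. They
were chosen once so that a control-preset population reproduces the
published control regime simultaneously: population mean speed near
0.06 μm/s; about 10% of tracks with mean speed above 0.14 μm/s, so that
the 90th percentile of the control population sits at the fast-mover
threshold; fast-class recovery by that fixed threshold with sensitivity
and specificity above 0.9; and a slow tail thin enough above 0.14 μm/s
(≈0.2–0.3%) that the patient preset's small fast fraction is not swamped
by false positives. The resulting per-track fast-class mean speed is
approximately normal with mean ≈0.23 μm/s and SD ≈0.056. All parameters
remain exposed in `motion_params()`.

## Geometry and placement

Processes are straight: the axial coordinate `s` is 0 at the soma and
increases distally; the transverse extent (0.5–1 μm, below the diffraction
scale of the rendered movies) is modelled as pure localization noise.
Default process length is 200 μm (observed range 150–300 μm). Moving
organelles are placed uniformly over the interval of start positions for
which the entire noise-free excursion stays inside the process; excursions
(tens of μm) are small relative to the process, and hard clipping at the
ends would silently convert transport time into immobility and bias every
class-recovery analysis. Immobile organelles are uniform over the process.

## Balanced class assignment

By default classes (and fast-track directions) are assigned by a
deterministic largest-deficit quota sequence: after any prefix of `k`
tracks each class count is within one of `k` times its fraction, and the
sequence for `n` tracks is a prefix of the sequence for any larger `n`,
so adding tracks never perturbs existing ones. For a validation
generator this is the right default: a recovered fast-mover fraction then
measures detection, tracking and classification, not the multinomial luck
of the class draw (which at `n = 1500` contributes an SD of ≈0.4
percentage points on a 2.3% fraction, comparable to the effect being
measured). `class_assignment = "multinomial"` restores independent draws.
Each track also owns a deterministic RNG substream derived from the
master seed, so simulations are reproducible track by track.

# Imaging and rendering

The default acquisition matches the study design: frames every 2 s for
4 min (121 frames), z-stacks collapsed by maximum-intensity projection
before analysis. Spots are rendered as lateral Gaussians
(`psf_sigma` 0.15 μm) whose photon budget (`photon_scale`, 500 per time
point) is spread across z slices with axial Gaussian weights and
normalised in the discrete domain, so the expected per-spot photon count
is identical in every frame. Poisson shot noise and Gaussian read noise
(SD 3) are added on top of a constant background (20 photons/pixel).
Movies round-trip through 32-bit float TIFF with a JSON sidecar carrying
the physical calibration.

For benchmark movies each simulated organelle is rendered in its own
transverse lane — a field of several parallel quasi-1D processes — with
the per-lane axial offset recorded, so tracked image coordinates map back
deterministically to the process axis (`layout_tracks()` /
`recover_s_coordinates()`). Lanes are spaced wider than the linking gate,
which keeps the benchmark's identity assignment unambiguous by
construction; tracking fidelity under ambiguity is tested separately with
crossing-track fixtures.

# Detection

Detection operates on the per-frame maximum projection: a
Laplacian-of-Gaussian band-pass at scale `σ = expected_diameter/(2√2)`
(matched filter for a blob of the expected 0.75 μm diameter), followed by
thresholding, 8-neighbour local maxima, merging of maxima closer than
`min_separation` (the brighter survives; plateau ties break
deterministically in row-then-column scan order), and subpixel refinement
by a background-subtracted intensity-weighted centroid over a window of
about one diameter. The automatic threshold is `median + 5·MAD` of the
filtered response, with the robust scale floored at 2% of the response
range — the floor matters only for near-noiseless images, where the MAD
of an essentially flat response would otherwise admit every numerical
ripple.

# Linking and the completeness filter

Consecutive frames are linked by exact optimal assignment (Hungarian
algorithm on a cost matrix with birth/death slots): the assignment
maximises the number of links with displacement within
`max_link_distance` (2.5 μm/frame ≈ 1.25 μm/s, above any plausible
transport burst) and, among those, minimises total squared displacement.
This makes linking independent of detection order, and it is tested
against exhaustive enumeration of all gated matchings. Gap closing by
linear interpolation is available (`max_gap`) but off by default, because
the analysis that follows deletes every track not observed in every frame
— the standard completeness filter applied before per-track speed
statistics. No motion-model prediction (e.g. Kalman) is used:
displacements per 2 s frame are small relative to spot spacing in this
regime.

# Motion metrics

Instantaneous speed is the frame-to-frame Euclidean displacement of the
projected 2D coordinates divided by the frame interval; a track's mean
speed is the arithmetic mean of that series (equivalently path length
over total time). A *saltatory event* is a maximal contiguous run of
speeds strictly exceeding 0.1 μm/s; *fast movers* have mean speed
strictly above 0.14 μm/s, the 90th percentile of the control population
("exceeding" is read as strict in both cases, so boundary values are
excluded, and `calibrate_fast_threshold()` re-derives the threshold from
any control population). Direction along the process axis is classified
by the sign of the net axial displacement with a ±0.2 μm stationary guard
absorbing localization noise. Organelle density is counted in the
half-open window `[20, 140)` μm from the soma by default (the 100 μm
window variant `[20, 120)` is a parameter away); half-openness avoids
double counting at window edges.

# Population statistics

All quantiles in the package use one convention: the check-loss
minimiser, returning the midpoint of the minimising interval when
`n·τ` is an integer. Group contrasts at each quantile level equal the
difference of the two groups' τ-quantiles — the coefficient a quantile
regression with a single binary covariate would estimate — with standard
errors and 95% CIs from a seeded case-resampling bootstrap (default 1000
resamples) and two-sided p-values from the normal approximation; the
analytic standard errors of any particular quantile-regression estimator
are estimator-specific, so the bootstrap is the portable choice.

Group tests use the cell line as the unit of analysis (five lines per
group in the study design, hence the printed `df = 8`): `t_from_summary()`
reconstructs the unpaired Student t from printed mean ± SEM, and
`t_from_values()` is the pooled-variance equivalent on raw values.
`chi_square_table()` is the Pearson statistic against independence.
`mixed_rm_anova()` computes the univariate mixed-model ANOVA from sums of
squares with subjects nested in groups: the between-subjects effect is
tested against subjects-within-groups, within-subject effects against the
subject × condition residual. With more than two within-subject
conditions SPSS-style multivariate output reports different error df
(e.g. `F(2, 7)` where the univariate decomposition gives `F(2, 16)`);
the univariate form is implemented because it follows directly from the
sums of squares and is exactly checkable against independent
decompositions. p-values are reported but the package's own validation
relies on statistics and estimates, never on p-values.

# Cell fluorescence quantification

Nuclei are segmented by Otsu thresholding plus connected components with
a minimum-area filter (touching nuclei merge — the documented default —
and a contrast guard returns no nuclei on foreground-free channels rather
than bisecting noise). The thresholded cell-mask area is partitioned
among nuclei by seeded region growing (Voronoi propagation on the
intensity landscape), and each cell's cytoplasm is its territory minus
its nucleus — the region between the nucleus and the cell edge.
Edge-touching cells are excluded, as in standard high-content practice.
The marker mean is computed per cytoplasm mask; intensities are in
arbitrary units, so only within-experiment contrasts are meaningful. A
minimum-cell-count gate (1000 cells in real screens) controls the
per-field aggregate and is relaxed for small synthetic fixtures. The
synthetic field generator places non-overlapping disc cells with per-cell
marker levels drawn from a condition-specific normal, providing exact
ground truth for recovery tests.

# What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume —
class mixture, run/pause saltation, directional bias, diffraction-limited
spots, Poisson + read noise, per-cell intensity contrasts — and passing
tests demonstrate that the pipeline recovers known parameters under that
structure. It does not emulate curved or branching neurites,
photobleaching, focus drift, spot-size heterogeneity, organelle
collisions/crowding in a shared lane, or the 13-field/well layout of real
high-content screens; agreement on synthetic data therefore bounds, but
does not guarantee, performance on real movies, and no claim of
equivalence with any proprietary detector (Imaris, Harmony) is made
beyond synthetic ground truth.

# Problem sizes and numerical choices

The test suite exercises the full rendered pipeline at 5 synthetic lines
× 48 tracks per condition, and the acceptance script at 5 × 300 per
condition with 0.25 μm pixels and a single z slice — sizes chosen so a
single-CPU run completes in minutes while the binomial confidence
intervals on recovered fractions remain informative; all are parameters,
and larger runs only tighten the intervals. Ground-truth-level checks
(no rendering) run at 5 × 400. Other numerical choices of record:
detections are sorted by descending filtered response with row/column
tie-breaks; degenerate inputs (zero-variance t, all-tied quantile
populations, zero-variance ANOVA strata, foreground-free segmentation
channels) return flagged results or errors rather than silent numbers;
movie intensities are stored as float32 after an exact
integer-offset/power-of-two rescale recorded in the sidecar.
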