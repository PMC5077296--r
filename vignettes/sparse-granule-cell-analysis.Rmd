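---
title: "Analysing sparse granule-cell activity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sparse granule-cell activity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsegc)
```

`sparsegc` implements the full analysis chain used to characterize dentate
gyrus granule cells (GCs) recorded juxtacellularly in freely moving rats:
most GCs are silent during exploration, and the small active minority can be
recognized both by a waveform signature (the spike "shoulder") and by its
dendritic architecture. This vignette explains each method, its assumptions,
the tunable parameters, and the design decisions taken where the procedure
was genuinely open.

## Spike-shoulder detection

Juxtacellular spikes of granule cells often show a transient deceleration —
a *shoulder* — on the repolarizing flank, visible as a local maximum of the
first derivative of the average spike trace. `detect_shoulder()` formalizes
the moving-average procedure:

1. The search window runs from the spike peak to the *spike offset*, the
   first sample at or below `offset_frac` (10%) of the peak.
2. The trace is compared to its centered moving average over `ma_win_ms`
   (0.25 ms). A guard of half the averaging window is excluded right after
   the peak: around a local maximum the trace trivially exceeds its own
   average (the average of a concave stretch lies below its center), so
   crossings inside the guard are degenerate. The first sample where the
   trace crosses its moving average *from below* marks a shoulder;
   `intersection_latency_ms` is the linearly interpolated crossing time
   minus the peak time.
3. If a shoulder is found, its prominence is quantified as the half-width of
   the local maximum of the first derivative nearest the intersection. The
   trace is boxcar-smoothed over `deriv_smooth_ms` (0.2 ms) and centrally
   differenced — the derivative of a boxcar-smoothed trace is itself
   smoothed with the same window, so a single pass covers both. Because the
   derivative is negative throughout the repolarization, the half-width is
   measured at half of the local maximum's *prominence* above the higher of
   its two flanking minima within the window, not at half of its raw value.

Properties worth knowing:

* The result is invariant under positive rescaling of the trace, and stable
  (to < 0.05 ms) across the 20-50 kHz acquisition range.
* On the noiseless synthetic template family, detection is a step function
  of the shoulder amplitude and the measured half-width is non-decreasing in
  it. A shoulder much narrower than the smoothing window can survive
  detection yet leave no resolvable local maximum in the smoothed
  derivative; the width is then reported at the sampling-resolution floor
  rather than from an unsmoothed signal, keeping the measurement path fixed.
* Edge handling of all moving averages is shrink-to-valid (no padding).

A note on the smoothing window: the derivative-smoothing span is quoted in
the original description of the procedure as a "200 ms" rectangular window,
which cannot be literal for a spike lasting one or two milliseconds; it is
interpreted here as 0.2 ms, consistent with the 0.25 ms scale of the
moving-average comparison, and is exposed as `deriv_smooth_ms`.

```{r shoulder}
wf <- gen_waveform(waveform_gen_params(shoulder_amp = 0.15))
detect_shoulder(wf)
```

## Waveform-based classification

`loo_classify_waveforms()` reproduces the classifier design used to assign
unidentified recordings to the GC class: a feed-forward network with one
hidden layer of 10 sigmoid units and a logistic output, leave-one-out cross
validation, early stopping when more than 6 consecutive validation checks
fail to improve, and ADASYN oversampling of the minority class on each
training fold. Design choices:

* **Features.** The input dimensionality was not specified in the original
  design; waveforms are peak-aligned, amplitude-normalized and resampled to
  64 points over a window of 0.75 ms before to 2.25 ms after the peak
  (`resample_len`). A repolarization-only variant (peak to offset) is
  available as the `segment` argument, mirroring the control showing that
  the repolarization phase carries the class signal.
* **Optimizer.** The original implementation used Levenberg-Marquardt
  backpropagation; the contract here is the architecture, the early-stopping
  rule, ADASYN and leave-one-out — not bit-level optimizer replication. The
  package trains with resilient backpropagation (iRprop-), which needs no
  learning-rate tuning, and holds out a stratified validation subset of 15%
  (`nn_val_frac`; the original validation-set construction is unstated).
* **ADASYN** follows the adaptive synthetic sampling construction:
  G = (n_maj − n_min)·β synthetic minority points (β = 1), allocated across
  minority points in proportion to the majority fraction among each point's
  k = 5 nearest neighbours, each point a uniform convex combination of a
  minority point and one of its minority nearest neighbours.

The published ~89% accuracy with 2 false positives and 3 false negatives
was measured on 47 real recordings that are not distributed with the paper;
the package's tests therefore validate the classifier on separable synthetic
families (100% expected), on label-shuffled nulls (chance expected), and for
monotone degradation with template noise — not against the 89% figure.

## Rate maps and spatial firing

`compute_rate_map()` implements the printed estimator on a 2.5 cm grid:
occupancy z(x) = Σ_t w(|x − x_t|)Δt and rate r(x) = Σ_i w(|x − x_i|) / z(x),
with w a Gaussian kernel of σ = 2.5 cm evaluated at pixel centers. The
kernel's normalization cancels between numerator and denominator, so an
unnormalized kernel is used, with no truncation radius. Pixels with smoothed
occupancy under 20 ms (`occ_min_ms`) are masked as unreliable. Positions are
the midpoint of the two head LEDs; frames with a missing LED are excluded,
never interpolated. A running-speed threshold of 1 cm/s — speed computed
from coordinates boxcar-smoothed over 600 ms — removes immobility epochs,
and spikes falling in removed epochs are excluded along with them (the
original text does not say whether spikes or only occupancy were filtered;
both-excluded is the coherent choice for a ratio estimator). Spikes are
mapped to the nearest tracking frame by timestamp.

The *visited* mask is taken from the raw, unsmoothed bin occupancy: under a
Gaussian kernel every pixel has positive smoothed occupancy, which would
make "fraction of visited pixels" identically 1. Coverage is therefore the
fraction of arena pixels the animal actually entered, and the valid mask is
the intersection of visited pixels with the 20 ms occupancy rule.

Firing fields (`detect_fields()`) are connected components of at least 12
pixels (`field_min_pixels`) exceeding 20% of the map peak
(`field_frac_of_peak`); contiguity is 8-connected by default
(`field_connectivity`, switchable to 4 — the convention was unstated and
8-connectivity is the common choice for blob labeling). A recording is
*spatially selective* when its fields cover strictly less than 20% of the
visited pixels. Inclusion for spatial analysis requires coverage above 70%
(square arenas) or at least two laps (annular maze, counted by angular
unwrapping around the arena center), more than 25 spikes, and a mean rate
above 0.1 Hz. Spatial information uses the Skaggs bits-per-spike form
SI = Σ p_i (r_i/r̄) log2(r_i/r̄), which the original analysis cites without
printing.

```{r spatial}
ses <- gen_session(field_gen_params(), seed = 3)
spatial_report(ses$tracking, ses$spikes)
```

## Morphometry

`assign_branch_orders()` decomposes a dendritic tree (read from SWC with
`read_swc()`; branch orders are always recomputed from topology, never read
from file) into ordered segments: order 1 from the soma to the first
branching node, incrementing at every branching node; unbranched
continuation nodes do not increment the order, and at a trifurcation all
children increment once. First-order length is measured from the *soma
center* (the more reproducible convention); the soma-edge alternative is
available via `primary_from`, mirroring the reported control that the
convention does not drive the classification. Lengths are 3-D path lengths,
uncorrected for tissue shrinkage.

`morph_features()` returns the ten primary features used downstream — total
dendritic length, per-order lengths for orders 1-7 (orders beyond 7
contribute to the total but have no dedicated slot), number of primary
dendrites, number of endings — plus the branching index (endings/primaries),
the complexity index (Σ branch-tip orders + number of tips) × (total length
/ number of primaries), an estimated total spine count when per-order spine
densities are supplied, and the soma position within the granule-cell layer
(0 at the deep, hilar border; 1 at the superficial border) via
`soma_layer_position()`.

## The sparse logistic classifier

`nested_loo_classify()` reproduces the elastic-net logistic classification
of active versus silent cells. The penalized deviance is

-(1/n)·loglik + λ·[(1−α)/2·‖β‖² + α·‖β‖₁],

so α = 1 is the lasso (the mixing convention of the implementation family
the original analysis used); the solver is a coordinate-descent IRLS written
for this package and cross-checked against an independent implementation in
the test suite. The λ path holds 100 log-spaced values from λ_max (the
smallest penalty that zeroes all weights) down by a factor 10⁻⁴ — both
unstated originally and exposed as `enet_nlambda` and
`enet_lambda_min_ratio`. All features are z-scored with statistics computed
on training rows only, inside every fold. The inner cross-validation is
leave-one-out when the training fold has at most 20 rows (the regime of the
13-cell dataset) and stratified 10-fold otherwise; λ is chosen by the 1-SE
rule — the strongest penalty whose mean inner-CV deviance is within one
standard error (computed across inner folds) of the minimum. Weights are
reported as mean ± SEM across the outer leave-one-out fits, per α in
{0.05, 0.1, 0.5, 0.9, 0.95}.

One behavioural subtlety is handled explicitly: with strongly shrunk models,
leave-one-out evaluation has a known anti-bias — under exact class balance
an intercept-only model always predicts the training fold's majority class,
which is the class *opposite* to the held-out cell, pushing chance-level
accuracy far below 50%. Held-out predictions are therefore thresholded at
the training fold's positive-class fraction (equivalently, the linear
predictor is compared to the null intercept) instead of probability 0.5.
With informative weights this shifts the boundary negligibly; on null data
it restores calibration, which the test suite verifies (mean accuracy at
chance over 100 null cohorts; permutation p approximately uniform).

`permutation_test()` shuffles the labels and repeats the entire nested
procedure (500 runs by default, at α = 0.1 only), reporting
p = #{runs with accuracy ≥ observed} / runs — the printed definition, with
no +1 correction; an exact zero is reported as below 1/runs.

The per-cell feature table of the 13 identified cells is not distributed
with the text the package was built from. `read_feature_csv()` loads such a
table when available; the package's own validation uses synthetic cohorts
matched to that design (7 silent / 6 active, effects on orders 2-3 versus
5-6), on which the accuracy spread across the five α values is at most one
cell, mirroring the reported α-insensitivity.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable without the original
recordings.

* **Waveforms** (`gen_waveform()`): a positive Gaussian spike (σ = 0.3 ms)
  minus a delayed after-hyperpolarization Gaussian, sampled at 40 kHz by
  default; the shoulder is an additive Gaussian bump (amplitude s, center
  0.4 ms after the peak, σ = 0.08 ms) — the analyses are agnostic about the
  shoulder's biophysical origin, so an additive bump is the minimal model.
  The defaults place the 10%-of-peak offset near 0.55 ms after the peak so
  the default shoulder delay lies inside the detection window, and give a
  spike half-width of ~0.7 ms, in the granule-cell range. With s = 0 the
  repolarization is strictly monotone, so the detector's false-positive
  behaviour is testable analytically.
* **Sessions** (`gen_session()`): an Ornstein-Uhlenbeck velocity walk
  (mean speed 15 cm/s, relaxation 0.8 s) reflected at the arena boundary —
  smooth and speed-controllable, which is all the tracking model requires —
  sampled at 25 Hz, with two LED positions 3.5 cm apart whose midpoint is
  the true position; spiking is an inhomogeneous Poisson process
  λ(x) = baseline + peak·exp(−‖x−c‖²/2σ_f²) realized by thinning. Defaults
  (600 s, peak 5 Hz, σ_f = 8 cm, baseline 0.1 Hz, 70×70 cm arena) give
  sessions that pass the published inclusion rules.
* **Dendritic trees** (`gen_morph_cohort()`): binary trees with one deep
  primary whose per-order segment counts follow the branching probabilities
  with systematic rounding, and shallow extra primaries. This makes
  per-order counts nearly deterministic, as in mature GCs, which reliably
  reach orders 5-7 with 12-18 endings and ~2.2 mm total length under the
  defaults. Class effects shift the targeted orders' mean lengths by a
  stated number of reference SDs — the between-cell SD of that order's total
  length under base parameters, estimated once from a fixed-seed internal
  simulation — while freezing the per-segment SD, so "a k-SD effect"
  separates the class means by k baseline SDs without inflating within-class
  variance.

None of the generators models bursting, theta rhythmicity, electrode drift,
tracking dropouts, reconstruction truncation, or inter-animal variability.
Passing tests on synthetic data therefore demonstrate that the *procedures*
are implemented correctly and recover known ground truth under their stated
assumptions — not that real recordings would yield any particular accuracy.
The published figures that depend on the unavailable raw data (the ~89%
waveform-classifier accuracy, the 18-of-21 shoulder prevalence, the exact
~85% on the 13 identified cells) are treated as context, not as reproduction
targets.

## Numerical choices and degenerate inputs

* Moving averages shrink to the valid range at trace ends; windows are
  converted to an odd number of samples.
* Crossing times and half-widths are linearly interpolated between samples.
* `detect_shoulder()` requires a unique positive peak and at least 0.5 ms of
  samples after it; a flat trace or a repolarization that never reaches the
  offset raises an error.
* Rate-map pixels are half-open intervals [iΔ, (i+1)Δ) with the origin at
  the arena's lower-left corner; coordinates are in cm.
* Fisher's exact test uses the sum-of-no-more-probable-tables two-sided
  definition (two-sided conventions differ between implementations); a zero
  margin yields p = 1. The Mann-Whitney test is exact for group sizes up to
  8 without ties (the identified-cell group sizes), normal-approximated with
  tie correction otherwise.
* All randomized operations take an explicit integer seed and are fully
  deterministic given (input, configuration, seed).

## Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make the statistical assertions meaningful while staying
quick: 50 sessions of 600 s for field recovery; cohorts of 20 cells per
class for effect recovery and 10 per class (100 cohorts) for the null; 50
null datasets of 8 cells at 200 permutations each for permutation-test
calibration; and 20-item waveform sets for the classifier checks.
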