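# sparsegc

Analysis pipeline for juxtacellular recordings and morphological
reconstructions of dentate gyrus granule cells (GCs). In the dentate gyrus
only a small minority of GCs is active during spatial exploration; `sparsegc`
implements the complete chain of analyses used to characterize that sparse
population:

* **Spike-shoulder detection** — GC spikes carry a transient deceleration
  ("shoulder") on the repolarizing flank. `detect_shoulder()` finds it as the
  first upward crossing between the average spike trace and its 0.25 ms
  moving average within the peak-to-offset window, and quantifies it as the
  half-width (at half prominence) of the corresponding local maximum of the
  first derivative.
* **Waveform classification** — `loo_classify_waveforms()`: a 10-unit
  single-hidden-layer network with early stopping after 6 validation
  failures, ADASYN minority oversampling, and leave-one-out cross-validation
  over peak-aligned, resampled average waveforms.
* **Spatial firing** — `compute_rate_map()` implements the kernel estimator
  z(x) = Σ_t w(|x−x_t|)Δt, r(x) = Σ_i w(|x−x_i|)/z(x) on a 2.5 cm grid with
  a σ = 2.5 cm Gaussian kernel, a 1 cm/s running-speed filter and a 20 ms
  occupancy mask; `detect_fields()` segments place fields (≥ 12 contiguous
  pixels above 20% of the map peak), with spatial coverage, selectivity
  (< 20% of visited pixels), Skaggs spatial information
  SI = Σ p_i (r_i/r̄) log₂(r_i/r̄), ISI histograms and spike
  autocorrelograms.
* **Morphometry** — `read_swc()` + `assign_branch_orders()` +
  `morph_features()`: branch-order decomposition (order increments at each
  branching node), per-order dendritic lengths, primary dendrites, endings,
  branching and complexity indices, spine-count estimates, and the soma
  position within the GC layer.
* **Sparse logistic classification** — `nested_loo_classify()`: elastic-net
  penalized logistic regression (coordinate descent, α ∈ {0.05, 0.1, 0.5,
  0.9, 0.95}) over the ten primary dendritic features, nested leave-one-out
  cross-validation with the 1-SE penalty rule, per-feature weight mean ± SEM
  across folds, and a label-permutation significance test
  (`permutation_test()`, 500 runs at α = 0.1).
* **Cohort statistics** — `classify_activity()` (> 60 s inclusion; silent =
  rate < 1/60 Hz), `cohort_proportions()`, `fisher_exact_2x2()` and
  `mannwhitney_2s()`.
* **Synthetic data** — `gen_waveform()`, `gen_session()` (Ornstein-Uhlenbeck
  trajectories with inhomogeneous-Poisson place-field spiking) and
  `gen_morph_cohort()` (stochastic dendritic trees with controlled class
  effects), so every stage runs and is validated without raw recordings.

## Worked example

```r
library(sparsegc)

# a 600 s open-field session from a place cell (peak 5 Hz, sigma 8 cm)
ses <- gen_session(field_gen_params(), seed = 3)
spatial_report(ses$tracking, ses$spikes)
#> <spatial_report> coverage 0.99, 1 field(s), selective=TRUE,
#>   SI 1.43 bits/spike, included=TRUE (ok)

# shoulder detection on a synthetic average spike with a 0.4 ms shoulder
detect_shoulder(gen_waveform(waveform_gen_params(shoulder_amp = 0.15)))
#> <shoulder_result> detected; latency 0.309 ms, shoulder width 0.047 ms,
#>   spike width 0.689 ms

# active vs silent classification from dendritic morphology
coh <- gen_morph_cohort(morph_gen_params("active", effect_size = 3,
                                         effect_orders = 5),
                        morph_gen_params("silent"), 20, seed = 42)
rep <- nested_loo_classify(coh$features, coh$labels, run_config(),
                           alphas = 0.1, seed = 1)
rep
#> <morph_class_report> n=40 cells, leave-one-out accuracy:
#>   alpha=0.1   92% (37/40 correct)
```

The session report says the simulated cell passes the spatial inclusion
rules, fires in a single place field covering under 20% of the visited
pixels (hence "selective"), and conveys ~1.4 bits of positional information
per spike. The shoulder result reports the peak-to-intersection latency
(close to the generator's 0.4 ms ground truth) and the derivative half-width.
The classifier output is the fully cross-validated accuracy of telling
active from silent cells when the order-5 dendritic length carries a 3-SD
class effect.

A thin command-line dispatcher over the same functions is installed as
`exec/sparsegc` (subcommands `simulate`, `shoulders`, `ratemap`, `morpho`,
`classify-morpho`, `cohort-stats`).

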