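---
title: "Designing stimulation protocols that target global slow oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing stimulation protocols that target global slow oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sostim)
```

## The problem

Slow oscillations (SOs, 0.5–1.5 Hz) during NREM sleep are causally linked to
overnight memory consolidation, and closed-loop transcranial
alternating-current stimulation (cl-tACS) timed to ongoing SOs can enhance
them. SOs are not spatially uniform, however: some are *global* (co-detected
on nearly all scalp electrodes within a short delay), others are restricted
(frontal or local), and the global ones carry the strongest association with
memory benefit. A stimulation protocol that only matches SO timing and
frequency, but not the spatial pattern of current flow, may therefore miss
its target.

`sostim` implements a model-based design loop that targets global SOs by
their full space-time signature:

1. **Detect** SO events per electrode in stage-scored sleep EEG.
2. **Cluster** electrode co-detection patterns into Global / Frontal / Local
   types.
3. **Represent** both sleep SOs and candidate stimulation paradigms as
   time-by-region current-density (CD) matrices — the common currency of the
   whole pipeline.
4. **Train** a bagged-trees classifier of global vs non-global CD profiles
   and score every CD feature by its one-way ANOVA F value.
5. **Optimize** each candidate paradigm's waveform parameters with a genetic
   algorithm (GA) so its simulated CD matches the average global-SO CD under
   the ANOVA-F feature weights.
6. **Select** the paradigm whose optimized CD the classifier assigns the
   highest posterior probability of being global.

## The CD representation

A CD matrix covers a 1-s window centred on the SO trough (−500 ms to
+500 ms), discretized at a bin width `dt` of 20, 50, 100 or 200 ms, over 17
brain regions (eight left/right-paired structures — neocortex, hippocampus,
thalamus, caudate, putamen, pallidum, amygdala, nucleus accumbens — plus the
unpaired brainstem). At `dt = 20` ms the matrix has 50 × 17 = 850 elements.
Flattened feature vectors are always **time-major** (all regions of bin 1,
then bin 2, …); a single feature-index function (`cd_feature_grid()`) is
shared by the classifier, the weights and the optimization objective, so the
ordering cannot drift between consumers.

CD units are arbitrary but must be consistent: the absolute scale would be
fixed by a forward head model, which is deliberately outside this package
(see *Scope* below). The synthetic transfer operator is normalized to unit
mean magnitude over a probe montage set so that defaults are on a sane
scale; the weighted correlation (WCC) is scale-invariant, while the weighted
MSE and the GA objective ε are scale-covariant, which is documented where
they are defined.

## Detection criteria and artifact screens

Detection runs per channel on the 0.1–4 Hz zero-phase band-passed signal
(second-order Butterworth, applied forward and backward; the first and last
2 s are excluded from candidate search as settling margin). A candidate
event runs from a positive-to-negative zero crossing, through the negative
half-wave, to the *next* positive-to-negative crossing — this extent makes
the range and total-duration criteria meaningful alongside the half-wave
criterion. Criteria: trough ≤ −80 µV; max-minus-min range ≥ 80 µV over the
event; negative half-wave 300–1000 ms; total duration ≤ 10 s.

Two standard muscle-artifact screens run on the raw signal: 26.25–32 Hz
power in 4-s bins against 4× the median of the 45 surrounding bins (about
3 min; at record edges the available part of the window is used, minimum
11 bins, and a zero median never flags), and 4–50 Hz power in 5-s bins
against 6× the per-channel median over all bins. Bin "power" is RMS by
default and configurable (`power_measure`), since variance or summed
absolute amplitude are equally defensible readings; the flag thresholds are
ratios, so the choice mostly washes out. Events overlapping flagged bins or
scorer-excluded epochs are discarded.

Amplitude-outlier screening is two-pass: event trough amplitudes are
referenced to the mean signal within ±10 s of the trough, and events more
than 4 SD above the mean of that statistic are discarded first per
electrode, then pooled across electrodes. The referenced amplitude is used
*for screening only* — reported event fields keep the filtered-signal
trough. Electrodes with a single event skip the per-electrode pass (the SD
is undefined). Stage membership requires the epochs containing both event
start and end to carry the requested stage label.

## Clustering and type labels

Each detected SO seeds a binary co-detection row over the head electrodes
(1 where some event on that electrode lies within a symmetric 400 ms
trough-to-trough delay — the delay is symmetric because the underlying
propagation can run either way). Rows are clustered with k = 3 k-means under
Hamming distance: because the data are binary, centroid updates are
per-electrode majority votes (ties resolved toward 1), which keeps centroids
binary and makes the Lloyd cost provably non-increasing; clusters emptied
mid-iteration are re-seeded with the worst-fit row. The best of 200 seeded
random restarts (up to 10,000 iterations each) by total Hamming cost wins.

Cluster labels are assigned by centroid coverage: the centroid with the
greatest mean co-detection is **Global**; of the remaining two, the one with
the larger frontal-minus-posterior mean is **Frontal**; the last is
**Local**. Ties for Global fall to the larger cluster, with a warning. The
frontal/posterior partition is an explicit input, so the rule adapts to any
montage.

## Classifier and feature weights

The classifier is a bagged ensemble of 100 regression trees on the 0/1
class encoding: each tree is grown on a with-replacement bootstrap with all
features available at every split, each leaf stores the class frequency of
its bootstrap sample, and the ensemble posterior is the average of per-tree
estimates. This construction means uninformative features yield a posterior
equal to the class prior rather than a degenerate vote. Performance is
summarized by the Matthews correlation coefficient (MCC), which stays
informative under the roughly 1:2 global:non-global imbalance of sleep data;
cross-validation is stratified 5-fold with the out-of-fold predictions
pooled into a single confusion matrix (pooling is the stable choice for
imbalanced data). Hyperparameters can be chosen by a seeded randomized
search over minimum node size and features-per-split with inner
cross-validation (`tune_so_classifier()`); the default training uses fixed
values (`min_node = 5`, all features per split), which is plain bootstrap
aggregation.

Feature weights are the per-feature one-way ANOVA F values between the two
classes, computed once from the training CD store and shared by the GA
objective and the reporting metrics. On data with trough-concentrated class
differences, the weights localize around the trough, concentrating the
optimization effort where global and non-global SOs actually differ.

## Waveforms, forward model and objective

Four waveform families span the 1-s stimulation window: a sinusoid
(4 parameters), a sum of three sinusoids (10), a duty-cycled square wave
(5) and a shifted cubic polynomial (5). The square wave is +1 for the first
`D` percent of each period; phases are in radians. GA search bounds:
amplitudes and offsets in [0, 1], frequencies in [0.01, 4] Hz, phases in
[−π, π], duty cycle in [0, 100] %, polynomial coefficients in [−1, 1].
Waveforms are evaluated on a 0.1 ms midpoint grid and averaged within
`dt`-wide bins; binning is linear, and the bin means agree with closed-form
integrals to well below 1e-4 relative error.

The forward model is linear by construction: a montage (four electrodes, one
per scalp quartile, two anodal and two cathodal so voltages sum to zero)
maps to a 17-region CD vector per unit waveform amplitude, and the CD of a
paradigm is that vector scaled by each bin's mean amplitude. Real transfer
vectors would come from a finite-element solver and can be imported
(`transfer_model_from_table()`, `read_transfer_csv()`); the bundled
synthetic operator draws per-region Gaussian-process fields over the 2-D
electrode layout so nearby electrodes produce correlated vectors, and
polarity reversal negates them.

The GA objective is ε = Σᵢ ωᵢ d(xᵢ, x*ᵢ) / Σᵢ ωᵢ over flattened features,
with d the squared difference by default. The source formulation leaves the
residual transform implicit; squared error is adopted because an un-squared
signed residual would be unbounded below as an objective, and the same
reading is applied to the weighted MSE (whose printed leading 1/n would
double-normalize against Σw and is therefore dropped — this affects only
the absolute WMSE scale, not any ranking). Both metrics expose
`loss = "absolute"` as an alternative. The WCC is the weighted Pearson
correlation; with equal weights it reduces exactly to `cor()`.

## The genetic algorithm

The GA minimizes ε over the family's parameter box: tournament selection
(size 2), blend crossover on 80% of the non-elite offspring, bounded
Gaussian mutation whose SD tightens from 15% of each parameter's range to
1.5% over the run, and elitism of 2 (which makes the best-fitness trace
non-increasing). Termination follows two rules: stop when the average
relative change of the best fitness over 50 consecutive generations is at
most 1e-6, or at 100 × (number of parameters) generations. The operator
suite is this package's choice within the "genetic algorithm" contract; the
termination rules are fixed. Fitness evaluation is vectorized over the
population (one matrix evaluation per generation), which is what makes
grid-scale optimization affordable. Per-cell seeds in `optimize_grid()` are
derived from the master seed and the cell index, so grids are reproducible
and order-independent, and failed cells are recorded with their reason
rather than dropped.

## What the synthetic generators emulate — and what they do not

The sleep dataset behind this method is restricted, so every input can be
synthesized:

* `synth_eeg()` plants biphasic SO pulses (negative then positive
  half-sine, nominal trough −120 µV, 500 ms negative half-wave) of three
  spatial types — global (all channels, delays spanning ≤ 300 ms), frontal
  (frontal channels), local (a seed channel and its two nearest
  neighbours) — on 1/f-shaped background noise (12 µV RMS default) over a
  16-channel layout at 128 Hz. Types are equally frequent, giving the
  ~1:2 global:non-global label imbalance reported for real sleep data.
  Default duration is 240 s at 5 events/min, which is ample to estimate
  detection precision/recall tightly while keeping the full test suite
  fast.
* `synth_cd_dataset()` produces labeled CD feature sets whose class
  difference is a mean shift (3 noise-SD by default) confined to features
  within ±100 ms of the trough in six SO-relevant regions, emulating the
  empirical pattern that near-trough CD is what discriminates global SOs.
* `synth_transfer()` stands in for the forward solver as described above.
* `synth_cd_paradigms()` anchors a training set to a known paradigm's CD so
  the end-to-end loop has a recoverable ground truth.

These generators are deliberately idealized: noise is stationary and
Gaussian-ish, planted SOs are exactly biphasic, channel covariance comes
only from shared events, and the "source estimation" step is replaced by
construction. Passing tests therefore demonstrate that the pipeline's logic
is correct and self-consistent — criteria applied exactly, clusters and
classes recoverable at stated effect sizes, the GA able to invert the
forward model — not that the method will achieve any particular performance
on real polysomnography, where artifact structure, non-stationarity and
source-estimation error dominate.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses `signal::filtfilt` with a second-order
  Butterworth design; edge settling is excluded by a 2-s margin rather than
  a filter-length rule because IIR impulse responses have no finite length.
* Ratio-based artifact screens never flag when the reference median is
  exactly zero (all-quiet records produce empty masks).
* `mcc()` returns 0 with a warning when a confusion-matrix margin is zero;
  `wcc()` refuses zero weighted variance rather than returning NaN.
* ANOVA F is 0 where both group means and variances coincide; exact
  within-group constancy with distinct means is an error rather than an
  infinite weight.
* Hamming k-means majority ties resolve toward 1; assignment ties take the
  lowest-index centroid; fewer than k distinct rows is an error naming the
  deficiency.
* Stratified folds fall back to plain random folds when a class is smaller
  than the fold count (leave-one-out), and every training fold is checked
  for both classes.
* A montage whose transfer vector is zero yields a constant objective; the
  GA returns the zero-waveform fitness and the WCC is reported as `NA`
  (undefined variance) instead of failing.
* All seeds derived from a master seed stay below 2³¹ − 1.

## Scope and known limitations

Source estimation (lead fields, inverse solutions) and finite-element
forward solving are out of scope by design; the package consumes their
outputs via the CD store and transfer-table import paths. Sleep staging is
an input (hypnogram), not a computation. The montage search enumerates
one-electrode-per-quartile combinations from configurable candidate lists —
the package does not hard-code any particular montage count. Within-stage,
within-subject clustering is the API unit; pooling across subjects is left
to the caller. The end-to-end pipeline validates the design loop on
synthetic ground truth at deliberately modest sizes (three montages, one
waveform family, `dt` = 100 ms, GA population 80 — sizes chosen so the whole
loop, including ten seeded repetitions, stays comfortable on one CPU);
applying the loop to imported real CD data uses exactly the same functions
with larger grids and the default GA population of 200.

## A worked run

```{r pipeline, eval = FALSE}
library(sostim)
res <- run_pipeline(seed = 1)
res
glance(res$selection)
autoplot(res$target)          # the target CD heat map
autoplot(res$selection$results$candidate[[1]]$ga) # a GA fitness trace
plot_feature_weights(res$weights, dt_ms = 100)
```

The printed result reports the detected event count, the global-event
share, the cross-validated MCC, and the selected protocol with its
posterior, WCC and WMSE against the target. With the default configuration
the selected cell is the ground-truth paradigm.
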