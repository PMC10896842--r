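# sostim

Model-based design of closed-loop transcranial alternating-current
stimulation (cl-tACS) protocols that selectively target **global sleep slow
oscillations (SOs)**.

SOs (0.5–1.5 Hz NREM waves) drive overnight memory consolidation, and the
*global* ones — co-detected on nearly all scalp electrodes within ≤ 400 ms —
carry the strongest memory association. Stimulation that matches only SO
timing misses their spatial signature. `sostim` is for sleep/stimulation
researchers who want to engineer a tACS protocol whose simulated effect on
the brain reproduces the space-time current pattern of naturally occurring
global SOs.

## What it does

Both sleep SOs and stimulation paradigms are represented as time-by-region
**current-density (CD) matrices**: a 1-s window around the SO trough,
binned at Δt ∈ {20, 50, 100, 200} ms, over 17 brain regions (850 elements
at Δt = 20 ms). The pipeline:

1. **SO detection** per electrode in stage-scored sleep EEG: 0.1–4 Hz
   zero-phase filtering; events between consecutive positive-to-negative
   zero crossings with trough ≤ −80 µV, range ≥ 80 µV, negative half-wave
   300–1000 ms, duration ≤ 10 s; two muscle-artifact screens
   (26.25–32 Hz/4-s bins vs 4× the surrounding-bin median; 4–50 Hz/5-s bins
   vs 6× the channel median) and two-pass 4-SD amplitude-outlier screening.
2. **Co-detection clustering**: each SO seeds a binary electrode vector
   (co-detection within 400 ms); k-means with Hamming distance (k = 3, 200
   restarts) labels events **Global / Frontal / Local**.
3. **Classification**: a bagged ensemble of 100 regression trees on
   flattened CD features returns the posterior probability that a CD
   profile is global; performance is the Matthews correlation coefficient
   (MCC) under stratified 5-fold cross-validation, robust to the ~1:2
   global:non-global imbalance.
4. **Optimization**: for each candidate paradigm (montage of four
   electrodes, one per scalp quartile, two anodal/two cathodal; waveform
   family; Δt), a genetic algorithm tunes the waveform parameters to
   minimize the weighted discrepancy

   ε = Σᵢ ωᵢ (xᵢ − x*ᵢ)² / Σᵢ ωᵢ

   between the simulated CD *x* and the average global-SO CD *x**, where
   the weights ωᵢ are per-feature one-way ANOVA F values. Waveform families:
   sinusoid, sum of three sinusoids, duty-cycled square, cubic polynomial.
   The GA stops when the mean relative change of best fitness over 50
   generations is ≤ 1e-6 or at 100 × (number of parameters) generations.
5. **Selection**: every optimized paradigm's CD is classified, and the one
   with the highest posterior of "global" becomes the protocol; weighted
   correlation (WCC) and weighted MSE (WMSE) against the target are
   reported alongside.

Forward modeling (FEM) and source estimation are out of scope: the package
imports externally computed CD/transfer data, and ships a synthetic linear
transfer operator plus generators for planted-SO EEG and labeled CD
datasets, so the whole loop runs and validates without restricted sleep
recordings.

## Worked example

```r
library(sostim)

# synthetic sleep EEG with planted global/frontal/local SOs
se <- synth_eeg(seed = 42)
ev <- detect_sos(se$recording)
ev
#> # A tibble: 213 × 8
#>    channel t_start t_trough t_mid t_end trough_amp range_amp stage
#>    <chr>     <dbl>    <dbl> <dbl> <dbl>      <dbl>     <dbl> <chr>
#>  1 F4         14.6     14.9  15.1  16.2     -121.       202. SWS
#>  2 F8         14.6     15.0  15.3  16.1     -101.       157. SWS
#>  3 AF4        14.8     15.1  15.3  16.0     -126.       210. SWS
#> # ... 210 more rows

cl <- cluster_so_events(ev, se$frontal, se$posterior,
  electrodes = se$recording$channel_names, replicates = 50, seed = 7)
table(cl$events$so_type)
#> Frontal  Global   Local
#>      45     157      11
```

Each row is one detected SO on one channel: trough time and amplitude
(µV, ≤ −80 by criterion), peak-to-peak range, and the zero-crossing
anatomy of the wave. The clustering recovers the three planted spatial
types from co-detection patterns alone.

The full design loop — detection, clustering, target CD, feature weights,
classifier, GA grid, selection — runs end-to-end on synthetic ground truth:

```r
res <- run_pipeline(seed = 1)
res
#> <so_pipeline_result>
#>   events detected:    222
#>   global events:      171
#>   cross-val MCC:      0.95
#>   selected protocol:  +F3 +F4 -P3 -P4 | sine | dt 100 ms
#>   posterior:          1
#>   matches truth:      TRUE
glance(res$selection)
#> # A tibble: 1 × 8
#>   montage_key     kind  dt_ms       epsilon posterior   wcc       wmse no_global
#>   <chr>           <chr> <dbl>         <dbl>     <dbl> <dbl>      <dbl> <lgl>
#> 1 +F3 +F4 -P3 -P4 sine    100 0.00000000409         1 1.000    4.09e-9 FALSE
```

The classifier separates global from non-global CDs at MCC 0.95, the GA
drives the weighted discrepancy ε to ~4e-9, and the selected montage,
waveform family and Δt are exactly the cell the target was manufactured
from — the loop closes on its ground truth.

See `vignettes/global-so-targeting.Rmd` for the model, parameter meanings,
design decisions and limitations, and `inst/cli/sostim.R` for a thin
command-line front-end (`detect`, `cluster`, `pipeline` verbs).

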