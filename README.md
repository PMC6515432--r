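# caflux

Single-cell calcium activity is one of the earliest signals available to
embryonic cells deciding between neuronal phenotypes, but at these stages it
is irregular, low-amplitude, and badly served by the spike-template methods
built for mature neurons. `caflux` implements a threshold-agnostic analysis of
per-cell fluorescence traces for labs that image dissociated embryonic cells
(e.g. *Xenopus* neural ectoderm loaded with Fluo-4) and phenotype the same
cells afterwards by fluorescence in situ hybridization (FISH): it quantifies
each cell's activity with four complementary metrics, scores each cell's
marker expression, and asks whether activity differs between
phenotype-defined populations under an effect-size-gated nonparametric test.

## The metrics

For each cell's trace `x_1..x_T` (after contiguity filtering and baseline
detrending):

- **Spike frequency at multiple thresholds.** A spike is a run of ≥ 2
  consecutive frames at or above `m·B`, where `B = mean(x)` is the trace
  baseline and `m ∈ {1.25, 1.5, 2, 3, 4, 8}`. Rates are reported in spikes
  per hour per threshold; analyzing all thresholds at once is the point, since
  which population "spikes more" can invert with `m`.
- **Average power.** `P = (1/T) Σ X_i²` with `X_i = x_i/mean(x) − 1`, a
  dimensionless index of fluctuation energy.
- **Hurst exponent.** Rescaled-range (R/S) estimate over dyadic
  non-overlapping windows with the Anis–Lloyd/Peters small-sample expectation
  removed: H ≈ 0.5 for memoryless traces, > 0.5 persistent, < 0.5
  anti-persistent.
- **Markovian entropy.** Traces are discretized into 4 quantile states; the
  Shannon entropies of the rows of the `n^k × n` transition matrix (k = 1)
  are summed and normalized by `n^k·log2(n)`, giving a predictability score
  in [0, 1].

Marker expression is quantified as the **FISH score** `F/F0`, each cell's
mean intensity over the average of the five dimmest cells on its plate, with
positivity called at 200% (and 300%, 400%) of background. Two populations are
compared per metric by a Bonferroni-corrected two-sample Kolmogorov–Smirnov
test, declared significant only if adjusted `p < 0.05` **and** `|Cohen's d| >
0.2`. Both randomization controls are included: value shuffling (which should
push entropy toward 1 and H toward 0.5) and pooled FISH-score label
randomization (which should find nothing).

A seeded synthetic-data generator (fractional Gaussian noise by
circulant embedding + Poisson spike plateaus on a drifting baseline + a
log-normal plate FISH model) provides ground truth for every stage.

## Worked example

Two 30-cell synthetic populations: "progenitor-like" cells (10 spikes/h,
amplitudes 1.25–2.5× baseline, memoryless noise) and "differentiated-like"
cells (3 spikes/h, amplitudes 2–8×, persistent noise, H = 0.8):

```r
library(caflux)

progenitor <- synthetic_spec(n_cells = 30, spike_rate_per_hour = 10,
                             spike_amplitude = c(1.25, 2.5),
                             spike_duration_frames = c(2, 3),
                             hurst_index = 0.5, seed = 101)
differentiated <- synthetic_spec(n_cells = 30, spike_rate_per_hour = 3,
                                 spike_amplitude = c(2, 8),
                                 spike_duration_frames = c(3, 6),
                                 hurst_index = 0.8, seed = 202)
pop <- generate_population(progenitor, differentiated, labels = c("sox2", "tubb2b"))

filt      <- filter_contiguous_tracks(pop$traces)   # >= 600 contiguous frames
detrended <- detrend_asls(filt$kept)                # AsLS baseline correction
metrics   <- compute_cell_metrics(detrended)
joined    <- join_phenotype(metrics, compute_fish_scores(pop$fish),
                            pop$roi_map, quiet = TRUE) |>
  dplyr::left_join(pop$markers, by = "cell_id")

run_comparison_design(joined, "posA_vs_posB", markers = c("sox2", "tubb2b"))
#>   metric_name   ks_statistic    p_adjusted cohens_d significant
#> 1 spikes_1.25x      9.57e- 1 0.0000000209     3.72  TRUE
#> 2 spikes_1.5x       7.75e- 1 0.0000247        2.22  TRUE
#> 3 spikes_2x         4.27e- 1 0.299           -0.947 FALSE
#> 4 spikes_3x         1   e+ 0 0.00000000308   -3.57  TRUE
#> 5 spikes_4x         1   e+ 0 0.00000000308   -3.05  TRUE
#> 6 spikes_8x         5.55e-17 1                0     FALSE
#> 7 average_power     1   e+ 0 0.00000000308   -2.90  TRUE
#> 8 hurst             6.07e- 1 0.00457         -1.49  TRUE
#> 9 entropy           1   e+ 0 0.00000000308    7.19  TRUE
```

Positive `d` means the first (sox2-positive) group is higher. The design
recovers the built-in structure: progenitor-like cells spike significantly
more at the 1.25× and 1.5× thresholds, differentiated-like cells at 3–4×
(the threshold-dependent flip), with higher power, higher Hurst exponent and
lower entropy in the differentiated-like group.

The shuffle control on the same traces destroys sequential structure, as it
should:

```r
shuffle_control(detrended, seed = 1)$summary
#>   metric   mean sd_cells sd_seeds
#> 1 hurst   0.477  0.0457        NA
#> 2 entropy 0.996  0.00178       NA
```

`run_pipeline()` drives the same steps from a YAML config over CSV inputs and
writes per-cell metric, FISH-score, comparison and correlation tables plus a
JSON manifest with cell counts at every filtering step; `run_controls()` adds
the randomization controls. `plot_trace()`, `plot_spike_rates()` and
`autoplot()` on a comparison table give the standard diagnostics.

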