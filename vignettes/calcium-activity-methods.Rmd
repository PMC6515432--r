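---
title: "Methods: calcium trace metrics and phenotype comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium trace metrics and phenotype comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`caflux` analyzes per-cell fluorescence time series from calcium imaging of
dissociated embryonic cells, together with per-cell FISH intensities measured
on the same cells after fixation. This vignette documents the model behind
each stage, the tunable parameters and why their defaults are what they are,
the numerical choices that are not forced by the problem, and what the
synthetic-data generator does and does not emulate.

## Input model and contiguity filtering

A recording is a frame × cell table of fluorescence intensities at a fixed
frame interval (default 8 s, i.e. 0.125 Hz; a 2 h session is ~900 frames).
Because cells move and tracking drops out, a cell's trace may have untracked
frames; these are encoded as blanks, never as zeros (zero fluorescence is a
legal measurement). A cell enters the analysis only if its longest run of
consecutively tracked frames reaches `min_frames` (default 600 frames =
45 min), and the trace is truncated to that run — the earliest one on ties.
Truncation, rather than gap interpolation, is deliberate: the Hurst and
entropy metrics quantify sequential structure, and interpolated samples would
inject artificial structure. Detrending runs after truncation, so the
baseline is estimated only on frames that are actually analyzed.

## Detrending (asymmetric least squares)

Slow multiplicative drift (focus, bleaching, dye loading) is removed with an
asymmetric least-squares (AsLS) baseline: b minimizes

    sum_i w_i (y_i - b_i)^2 + lambda * sum_i (d2 b_i)^2,

a Whittaker smoother with second-difference penalty, with weights
`w_i = p` where `y_i > b_i` and `1 - p` otherwise, iterated to a fixed point.
Small `p` makes b hug the trace from below: drift is absorbed, brief positive
transients (spikes) are not.

Parameters (all exposed): `smoothness` lambda = 1e5 — on ~900-frame traces
this gives the baseline an effective bandwidth of tens of minutes, far slower
than any spike but fast enough to track session drift; `asymmetry` p = 0.01 —
spikes occupy a small fraction of frames, so the baseline should treat
essentially all supra-baseline excursions as signal; `max_iter` = 10 — the
weight pattern stabilizes in a handful of iterations; if it has not, the last
iterate is returned with a warning rather than an error. Iterations also stop
when the baseline itself stops moving (relative RMS change below 1e-10),
which is the natural fixed point on noiseless traces where the weight pattern
can oscillate on floating-point ties.

The corrected trace is `y - b + mean(b)`: an additive correction that removes
the *variation* of the baseline while preserving the trace mean exactly
(`mean(corrected) = mean(y)` by construction). A ratiometric `y/b` correction
was rejected because every spike threshold downstream is defined as a
percentage of the trace mean; keeping the intensity scale makes those
thresholds directly interpretable, and the mean-preservation property is what
the per-cell metric tests assert.

## The four activity metrics

**Spike frequency.** The baseline is the mean of the (detrended) trace — a
deliberately simple definition suited to traces where activity is too
irregular for template matching. A spike at threshold `m` is a maximal run of
at least `min_duration_frames` (default 2) consecutive frames with value
≥ `m · mean`. Rates are spikes per hour, using the frame interval. Six
thresholds (1.25, 1.5, 2, 3, 4, 8 × baseline) are always computed: which
population shows higher rates can genuinely invert between low and high
thresholds, and the package treats that inversion as a result, not a
nuisance. Note that spike *run counts* need not be monotone in `m` (low
thresholds merge neighboring events); the count of supra-threshold *frames*
is monotone, and that is the invariant the tests check.

**Average power.** `P = (1/T) sum X_i^2`. By default `X_i` is the
mean-normalized fluctuation `x_i/mean(x) - 1`, making P dimensionless; raw
intensities would make P dominated by the DC offset and incomparable across
imaging sessions with different gain. A `power_mode = "raw"` switch restores
plain squared intensities for users who want the textbook quantity on a
single session.

**Hurst exponent (rescaled range).** For dyadic window lengths
`L = min_window, 2*min_window, ...` up to T/2, the trace is cut into
`floor(T/L)` non-overlapping windows; per window R is the range of the
cumulative sum of mean-subtracted values and S the sample standard deviation;
R/S is averaged over windows with S > 0. The estimate is
`H = 0.5 + slope of log2(mean R/S / E[R/S_L]) on log2(L)`, where `E[R/S_L]`
is the Anis–Lloyd/Peters expected rescaled range of an i.i.d. Gaussian series
of length L. The correction matters: the plain R/S slope on ~900-frame series
is biased upward by roughly +0.07 (white noise estimates near 0.57), while
the corrected estimator is centered (white noise ≈ 0.49–0.50) and reproduces
the package's shuffle-control target (≈ 0.47–0.49 on resampled spiky traces,
whose heavy-tailed marginals sit slightly below the Gaussian expectation).
`min_window` defaults to 16: starting the window schedule at 16 rather than 8
trades one regression point for noticeably better recovery of strongly
persistent series (fGn with H = 0.8 recovers to ≈ 0.72 rather than ≈ 0.71;
both 0.3 and 0.5 recover within 0.06). Windows do not overlap, and no
estimate is attempted with fewer than three usable window lengths or on
constant traces.

**Markovian entropy.** Values are discretized into `n_states = 4` empirical
quantile states; an `n^k × n` transition count matrix over `k = 1` histories
is built; each row becomes a probability distribution whose Shannon entropy
(base 2, with `0·log 0 = 0`) is summed over rows and normalized by
`n^k·log2(n)`, bounding the result in [0, 1]. Two conventions matter for
degenerate inputs: duplicate quantile edges (low-variance traces) are
collapsed, so fewer states are occupied while the normalization keeps the
nominal `n^k·log2(n)` — constant or near-constant traces therefore score near
0, which is the right reading of "fully predictable"; and rows with no
observed transitions contribute 0 — unvisited histories carry no evidence,
and penalizing them would make the ~0.996 i.i.d. ceiling unreachable (the
residual gap from 1.0 is the Miller–Madow-type small-sample bias of plug-in
entropy at ~225 transitions per row, about 0.004 with these settings).

## FISH scores and the phenotype join

Per plate, the background F0 is the mean intensity of the five dimmest cells
(ties broken by intensity then ROI ID, so F0 is deterministic); every cell's
FISH score is F/F0, and positivity at multiplier `m` is `score >= m`. The
default call is 2.0 (200% of background), with 3.0 and 4.0 evaluated in the
same pass because phenotype contrasts are examined at several expression
cutoffs. The five-dimmest definition is applied per plate — plates differ in
staining efficiency — and the `background_n = 5` is exposed but defaulted.
Calcium and FISH ROIs are linked by an explicit one-to-one ID map (the
product of manual co-registration); the join is inner, and unmatched cells on
either side are counted and reported rather than dropped silently.

## Statistics

Two-population comparisons use the two-sample Kolmogorov–Smirnov test
(asymptotic p, from `stats::ks.test`; a warning is raised under n = 20 per
group) with Bonferroni correction, `p_adj = min(1, p_raw × family_size)`.
The family is all comparisons launched by one design invocation (metrics ×
groups in that run), and `family_size` is recorded in every result row so the
correction is auditable. Significance requires both `p_adj < 0.05` and
`|Cohen's d| > 0.2` (pooled-SD d, Cohen's original form; 0.2/0.5/0.8 are the
conventional small/medium/large bands). The joint rule is conservative by
construction: the K-S test is sensitive to any distributional difference,
and the d-gate suppresses distribution-shape hits with negligible location
effect. With zero pooled SD and unequal means d is ±Inf; the row is flagged
and decided by p alone.

Expression-level association is reported two ways on the same pairs: Pearson
r, and the R² (`1 - RSS/TSS`) of a univariate penalized-spline GAM
(`mgcv::gam`, thin-plate spline, smoothing by GCV) of the metric on the FISH
score, which captures monotone-but-nonlinear and non-monotone dependence that
r misses. The spline basis dimension adapts to the number of unique scores
(k between 3 and 10). Stage-level expression fractions are compared with the
Kruskal–Wallis rank test; an all-identical response is reported as H = 0,
p = 1 rather than an error.

Two randomization controls validate the sequence-sensitive metrics:

- **Shuffle control**: each trace is resampled to its own length — with
  replacement by default, matching bootstrap-style "take the same number of
  values at random" semantics; a permutation mode (`replace = FALSE`) is
  provided, and the two are indistinguishable for this purpose since both
  destroy sequential order. Shuffled traces should score entropy ≈ 1 and
  H ≈ 0.5; the package's synthetic trace set lands at 0.996 ± 0.002 and
  ≈ 0.47–0.49. Summaries report the mean and SD across cells; with a single
  shuffle per trace the between-shuffle SD is reported as NA, never as 0.
- **Label randomization**: cells from two marker experiments are pooled,
  sorted by FISH score, and split into halves (sizes differ by at most one;
  score ties broken by a seeded draw). On data where activity does not follow
  the pooled score split, no comparison should pass the joint rule.

## The synthetic-data generator

`synthetic_spec()` + `generate_trace()/generate_population()` produce traces
as `baseline × (1 + drift(t)) + baseline × noise_sd × fGn(H) + spike pulses`,
with Poisson spike onsets, uniform amplitude in a stated range (multiples of
baseline) and uniform integer durations (≥ 2 frames). fGn comes from the
Davies–Harte circulant embedding (exact target autocovariance, unit variance,
seeded; spectral synthesis fallback with a warning if the embedding fails).
Defaults describe the acquisition the package targets: 900 frames at 8 s,
baseline 100 AU, linear drift of 20% of baseline over the recording (within
the regime the AsLS defaults remove), noise SD 5% of baseline. The two
standard study populations used in the tests and the acceptance script are
"progenitor-like" (10 spikes/h, amplitudes 1.25–2.5×, durations 2–3 frames,
H = 0.5) and "differentiated-like" (3 spikes/h, amplitudes 2–8×, durations
3–6 frames, H = 0.8) — parameter regimes chosen once to put spikes on both
sides of the 2× threshold and memory on both sides of H = 0.5.

Spike pulses are rectangular plateaus at `amplitude × baseline` (taking the
pointwise max with the underlying trace), not indicator-kinetics transients:
the spike definition downstream is threshold-and-duration based, so
rectangular truth makes count recovery exact; an exponential-decay shape is
available (`spike_shape = "decay"`) for realism checks. Overlapping pulses
are merged into one run in the ground truth, mirroring what any run-based
counter could ever see. FISH intensities are log-normal (strictly positive,
right-skewed, like real intensity data) around `score × background`, with
≥ 5 dim anchor cells per plate drawn just below the nominal background level
so the five-dimmest F0 is well defined.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: cell movement and tracking errors (validity
masks are generated clean), indicator saturation and photobleaching
nonlinearity beyond smooth drift, correlated multi-cell events (waves),
plate-to-plate staining variation beyond the single-plate FISH model, and
the heavy manual QC (ROI deletion) of real experiments. The controls and
recovery tests validate the *estimators*; they cannot validate image
segmentation or tracking upstream of the exported tables.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale by choice: 50-cell
trace sets for the randomization controls, 60 + 60 cells for the
two-population design, 2,000 replicates for null calibration of the joint
rule, 10,000 traces for the entropy range sweep, and 50 seeds per condition
for estimator calibration — sizes at which every stochastic assertion has
comfortable Monte Carlo margin while a full run stays in minutes. Every
stochastic procedure takes an explicit integer seed; identical seeds
reproduce identical values end to end, including CSV report bytes.

## Known limitations

- The R/S Hurst estimator, even corrected, compresses extreme H: strongly
  persistent series (true H = 0.8) estimate near 0.72 on 900-frame traces.
  Comparisons between populations are unaffected (the bias is shared), but
  absolute H values should be read with that compression in mind.
- The asymptotic K-S p-value is conservative with heavily tied samples (e.g.
  spike rates at high thresholds where most cells have 0); ties are the rule
  at the 8× threshold, where comparisons are rarely meaningful anyway.
- Bonferroni across a design's full family is strict; users who consider the
  metrics a priori separate can run designs per metric
  (`metrics = "hurst"`, etc.), which sets the family accordingly.
- The entropy's quantile binning assumes enough dynamic range to define
  quartiles; traces quantized to fewer than 4 distinct values occupy fewer
  states and score low entropy by convention, which should be remembered when
  analyzing heavily rounded exports.
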