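---
title: "Microstate analysis of emotional EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of emotional EEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstate)
```

## The microstate model

Spontaneous EEG does not wander continuously through topography space.
Over windows of roughly 80–120 ms the spatial configuration of the scalp
potential field stays quasi-stable, then switches abruptly to a new
configuration. These quasi-stable periods — *microstates* — are the unit of
analysis in this package: the continuous multichannel signal is reduced to
a sequence of labels drawn from a small set of template topographies, and
everything downstream (temporal parameters, transition structure, feature
tables for emotion classification) is computed from that sequence.

The pipeline has five stages:

1. **Preprocessing** (`preprocess()`): band-pass 1–45 Hz, notch 48–52 Hz,
   common average reference (CAR), optional downsampling. Filters are
   zero-phase forward–backward Butterworth designs (order 4 by default), so
   the timing of topographic events is not shifted; resampling is
   polyphase/anti-aliased. The filter family and resampler are exposed as
   configuration because nothing in the method depends on the particular
   design beyond standard EEG practice. Independent-component artifact
   removal is deliberately out of scope: the pipeline expects
   already-cleaned recordings.

2. **GFP peak extraction** (`gfp_curve()`, `extract_peak_maps()`). The
   global field power `GFP[n] = sqrt(sum_i (v[i,n] - vbar[n])^2 / C)` is
   the spatial standard deviation of the average-referenced map. At its
   local maxima the topography has the highest signal-to-noise ratio and is
   momentarily stable, so only the maps at GFP peaks enter clustering.
   Peaks are strict interior maxima; on a plateau the first sample wins
   (the choice is arbitrary and only needs to be deterministic). Banks
   pooled across recordings are capped at 1000 maps per recording by a
   seeded uniform subsample — uniformity preserves the topography
   distribution, and the cap keeps group-level clustering tractable.
   Maps are stored average-referenced but *not* norm-scaled, because the
   explained-variance weighting below needs the raw GFP.

3. **Polarity-invariant clustering** (`modified_kmeans()`). Microstate
   analysis of spontaneous EEG treats a map and its polarity reversal as
   the same state. Assignment therefore minimizes the orthogonal squared
   distance `d2 = x'x - (x'a_k)^2` (equivalently, maximizes the squared
   spatial correlation), and cluster centers are recomputed as the
   *sign-aligned* mean: each member is multiplied by the sign of its
   projection on the current center before averaging, then the center is
   re-centered and re-normalized. A literal mean is available
   (`align_mode = "literal_mean"`) but under polarity-invariant assignment
   it lets opposite-polarity members cancel, which is why sign alignment is
   the default. Iteration stops when labels stop changing (or at
   `max_iter`); the best of `restarts` seeded initializations by total GEV
   is kept; an emptied cluster is re-seeded from the worst-fitted map; ties
   always break to the smallest index. All randomness flows from one seed.

4. **Model-order selection** (`klgev_criterion()`, `select_k_optimal()`).
   The global explained variance
   `GEV = sum_n Corr(x_n, a_{l_n})^2 GFP_n^2 / sum GFP^2` grows
   monotonically with K, so the number of microstates cannot be read off
   the GEV curve directly; the interesting point is the *elbow* where
   adding states stops paying. The criterion normalizes the curve as
   `K^(2/C) GEV_K`, takes the first-order difference at interval 2
   (`DIFF_K`) — interval 2 damps single-step jitter — and forms the ratio
   `KL_K = DIFF_K / DIFF_{K+2}`. Before the optimum both differences are
   large, after it both are small, and exactly at it a large numerator
   meets a small denominator, so the optimum appears as the largest
   interior local peak of the KL series. Endpoints of the defined series
   are never selected: a series that starts at its maximum carries no
   evidence of an elbow on its left.

5. **Backfitting, smoothing, parameters** (`backfit()`,
   `smooth_window()`, `class_parameters()`). Every sample is labeled with
   the template of highest absolute spatial correlation (absolute by
   default, consistent with the polarity-invariant clustering; a signed
   mode exists). The label sequence is then smoothed (below), run-length
   segmented, and summarized per class by occurrence (segments/s), mean
   duration (ms), coverage, per-class GEV, mean GFP, mean |spatial
   correlation|, plus the row-stochastic transition matrix with zero
   diagonal.

## The K = 1 anchor in the scan

`scan_and_select()` fits every K in `k_min..k_max` and applies the
criterion. The ratio `KL_K` needs `DIFF_K` and `DIFF_{K+2}`, and `DIFF_K`
needs `GEV_{K-2}`, so a scan over `2..k_max` defines KL only from K = 4
upward — and K = 4, a common true model order, would sit on the endpoint of
the KL series and be unselectable. The package therefore anchors the GEV
series at K = 1 whenever `k_min <= 2`, using the principal topography (the
dominant eigenvector of the map scatter — exactly the K = 1 limit of
sign-aligned K-means). This extends the KL series one step down so that
`k_min + 2` is interior. The criterion itself is unchanged; when it is
applied to an externally supplied GEV table (`klgev_table()`), no anchor is
added and the table is used as given.

## Temporal smoothing: objective and calibration

Raw backfitting produces spurious one- or two-sample label flips wherever
the instantaneous field is weak. The windowed smoother relabels each sample
`n` to minimize

```
cost(n, k) - lambda * N_k(n),    cost(n, k) = d2(n, k) / (2 e (C - 1))
```

where `N_k(n)` counts same-labeled samples within `n-b..n+b` (excluding
`n`, truncated at the edges) and `e` is the mean residual variance of the
incoming labeling — the scaling that keeps `lambda` commensurate with the
fit term whatever the signal amplitude. Two implementation details matter:

* **Updates are simultaneous per pass**, not an in-place sweep. A sweep
  drags labels in the sweep direction and systematically over-merges
  (measured on the synthetic generator: ~18% mean-duration inflation from
  this artifact alone). Simultaneous updates can settle into a two-state
  cycle; the package detects the cycle and keeps the state with the lower
  total objective.
* **The default penalty is `lambda = 1` with `b = 3`.** Dissolving one
  segment boundary gains about `2 b (b + 1) lambda` agreement units, i.e.
  24 per boundary at `lambda = 1`, against a fit margin of roughly 10–15
  cost units per sample for a map at full field strength. Larger weights
  (e.g. `lambda = 5`) make the penalty dominate the fit for any segment up
  to ~7 samples, which wholesale-absorbs the short-lifespan tail of a
  realistic duration distribution and biases mean duration upward by
  ~20%; `lambda = 1` removes fit-free noise flips while leaving genuine
  short segments in place. On ground-truthed synthetic data this
  calibration recovers mean durations within a few percent (see the
  acceptance tests). Both parameters remain configurable.

The alternative smoother (`reject_short_segments()`, default threshold
30 ms) dissolves sub-threshold runs sample-by-sample into the neighboring
label with the higher absolute correlation. It is simpler to reason about
but inflates durations more, because merging is its only move.

## Feature tables

`windowed_feature_table()` cuts a recording into non-overlapping windows
(15 s by default — long enough for stable per-class parameter estimates,
short enough that several windows fit in a trial) and emits, per window:
occurrence, duration, coverage and per-class GEV (4K values), the flattened
K×K transition matrix (its zero diagonal is kept so the temporal block is
exactly `4K + K^2` wide for every K), and optionally mean GFP and mean
spatial correlation (2K more). With K = 10 and spatial features this is
160 columns; with K = 9, 135. Edge segments truncated by the window
boundary are counted; this keeps the identity
`coverage = occurrence * duration / 1000` exact on every window.
`band_power()` adds `5 C` columns of canonical band powers
(delta 1–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–45 Hz), estimated
by an averaged modified periodogram (Hann window, 2 s segments, 50%
overlap — conventional resolution/variance trade-off for these bands) and
integrated over each band so that band powers add up over tiling bands.

## Group comparisons

For rating-based designs (valence/arousal on a 1–9 scale), trials are
split high/low per dimension against a per-subject threshold — the mean of
the subject's own ratings by default, since subjects use the scale very
differently; a fixed threshold (default 5.0) and a per-subject median are
available, and a subject with constant ratings falls back to the fixed
value with a warning. Ratings exactly at threshold go to the low group (a
documented convention; some convention is needed and none is canonical).
The published self-adaptive threshold-reassignment procedure this stands in
for is not reproduced here; the per-subject-mean rule is a clearly labeled
substitute. Comparisons use the two-sided Wilcoxon rank-sum test at
alpha = 0.05 with no multiple-testing correction by default (an FDR option
exists but is off, matching the conventional raw-alpha screen).

## The synthetic generator

`simulate_recording()` plants known structure so every stage can be scored
against ground truth: K zero-mean unit-norm templates with pairwise
|correlation| < 0.3 (smooth random profiles, blended toward their symmetric
orthogonalization just enough to meet the bound); a semi-Markov label
sequence with geometric segment durations (memoryless — the sample-level
process is then first-order Markov; a truncated-Gaussian option gives a
more peaked duration histogram) and a configurable transition matrix;
an amplitude envelope `|sin(2 pi 10 t)|` (two GFP peaks per cycle, the
alpha-band GFP rhythm); and white sensor noise scaled to a target
signal-to-noise amplitude ratio, followed by CAR. Defaults: K = 4, C = 32,
200 Hz, 60 s, 100 ms mean lifespan (the middle of the typical range),
uniform switching, snr = 4.

What the generator does *not* emulate: 1/f background spectra, spatially
correlated sensor noise, volume-conduction leadfields, non-stationary
amplitude dynamics, or artifacts. Tests passing on this generator therefore
demonstrate the correctness and calibration of the algorithms under the
stated model, not performance on any real recording. Note also that the
envelope touches zero twice per cycle; at those samples the map is pure
noise (or exactly zero in the noiseless limit, where backfitting carries
the previous label forward), which is why even noiseless label recovery is
only ~99.5% rather than 100% — switches that land exactly on an envelope
zero are invisible in principle.

## Numerical conventions

* Ties in every argmax/argmin break to the smallest index.
* Templates are zero-mean and unit-norm; per-class GEV sums to total GEV
  to 1e-9; template polarity is a gauge freedom (flipping any template
  changes no assignment, GEV or scan value).
* A zero map (all channels equal) cannot be labeled; it inherits the
  previous label, or 0 (excluded from parameters) at the start of a
  recording.
* `DIFF_{K+2} = 0` leaves that KL entry undefined with a warning rather
  than propagating an infinity; a KL series with no interior peak raises
  an explicit no-peak error suggesting a wider grid.
* All stochastic entry points (subsampling, initialization, simulation)
  take explicit integer seeds and restore the caller's RNG state.

## Problem sizes used in the validation suite

The test suite validates the pipeline at deliberately modest scales chosen
for tight feedback loops: oracle comparisons enumerate instances up to 2^12
labelings; property checks run on banks of a few hundred maps; the
recovery experiment uses 120 s recordings at 200 Hz with 32 channels, one
deep run plus a 20-seed model-order recovery study. These sizes are the
package's own validation design; the algorithms themselves are routinely
run on hours of pooled EEG.

## Known limitations

* The KL-ratio criterion needs `GEV` at `K-2 .. K+2`, so the selectable
  range of a scan is `k_min + 2 .. k_max - 3`; scans must bracket the
  plausible optimum generously.
* Mean duration estimates remain mildly biased upward (a few percent)
  even at the calibrated smoothing weight, because fragmentation at
  low-GFP samples is corrected by merging only.
* The EDF writer quantizes to 16 bits against the per-channel range, as
  the format prescribes; round-trips are exact only to that quantization.
* Group statistics implement two-group rank-sum screens only; factorial
  designs and corrected families are out of scope.
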