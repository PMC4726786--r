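---
title: "Time-aligned brain-behavior files and unsupervised similarity search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aligned brain-behavior files and unsupervised similarity search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurospan)
```

## The problem

Neural decoding works from recordings in which brain activity (ECoG, EEG,
fMRI, ...) and the behavioral or stimulus record are aligned on one time
axis. `neurospan` provides three things around that idea:

1. a schema-based HDF5 **file format** in which time-series data, interval
   annotations (`timespans`, e.g. stimulus blocks) and point events
   (`timestamps`, e.g. spikes) live side by side in named groups on a common
   clock;
2. an **unsupervised similarity search** over such a file: given any time
   interval, find all other time windows whose high-gamma spatial pattern is
   significantly similar;
3. a label-based **ROC validation** of that search, plus a synthetic ECoG
   generator so the whole pipeline is testable without any external data.

## The file format

An HDF5 file holds a root `fileHeader` group (free experiment/subject
properties) and any number of data groups. Each group carries at least one
of `data` (a samples x channels matrix), `timespans` (start/end pairs, with
an optional parallel `labels` dataset) or `timestamps`, plus a `props`
subgroup with one dataset per property. Only `title` and `type` are
mandatory; `type` draws from a controlled but user-extensible vocabulary
(`ECoG`, `EEG`, `fMRI`, `stimulus`, `physicalMovement`, ...) shipped as a
YAML schema (`bb_schema()`). Unknown properties and types are preserved and
downgraded to warnings — a custom schema is legitimate, so the validator
never hard-fails on vocabulary.

Conventions this package fixes (the format itself is silent on them, so they
are documented package decisions):

* all times are seconds as 64-bit floats, 0 = recording start; intervals are
  half-open `[start, end)` so adjacent blocks never double-count a boundary
  sample;
* `data` is oriented samples x channels (time down the rows); the validator
  flags the transposed-looking case only as a warning, since short
  many-channel recordings do exist;
* groups are kept in name order. HDF5 enumerates links alphabetically, so a
  canonical order is the only way `read` after `write` can reproduce the
  model field for field — which it does, bit-exactly for float payloads;
* `validate_bbfile()` never throws: it returns a tibble of violations with a
  severity per row. `write_bbfile()` refuses models with *errors*;
  `read_bbfile(strict = FALSE)` returns a best-effort model with the
  violations attached, so exploration and search still work on imperfect
  files.

The grouping advisor `suggest_grouping()` encodes the format's heuristic:
two blocks of data belong in one group iff they share time span, sampling
rate and kind (same recording modality, or same behavior/stimulus type).

## Features: multi-timescale high-gamma band power

ECoG/EEG groups are segmented into non-overlapping windows tiling the
recording from t = 0 at each of four durations — 0.5, 1, 1.5 and 5 s by
default — with a trailing partial window discarded. Per window and channel
we take the FFT of the raw samples (rectangular window, no detrending, no
taper), sum the squared coefficient magnitudes over all bins whose center
frequency lies in [60, 100] Hz inclusive, and z-score each channel across
that duration's windows. A window of *n*-channel data thereby becomes a
single length-*n* feature vector regardless of sampling rate or duration —
1 s of 64-channel data at 10 kHz compresses from 640,000 numbers to 64.

Numerical choices, all of which cancel or are documented so oracles match:

* the transform is unnormalised (`stats::fft`); any multiplicative constant
  is removed by the z-score;
* band edges are inclusive on bin centers; the DC bin is outside the band by
  construction;
* the z-score uses the population denominator (divide by the window count),
  configurable to the sample convention;
* a channel with identical band power in every window (e.g. a dead
  electrode) z-scores to all zeros and is flagged `constant` rather than
  producing NaNs, so downstream correlations stay defined;
* a duration yielding fewer than two windows cannot be z-scored and is
  skipped with a warning.

## The sparse significance-span index

At each timescale, the similarity between two windows is the Pearson
correlation of their feature vectors across channels. Storing all W^2
correlations is infeasible for large archives, so the index binarises them:
a (query, target) pair is kept iff r > 0 **and** its two-tailed p-value is
at most 0.05 (no multiple-testing correction — the threshold is a display
criterion, not an inference). Kept pairs are run-length encoded per query
row as maximal runs of consecutive significant targets, each run holding its
starting index and p-values. Worst case the encoding is linear in the number
of significant pairs (one singleton run each, as the adversarial
alternating pattern in the tests shows); in practice task-related activity
clusters in time, so runs are long and few.

The p-value uses the exact bivariate-normal null via the t transform
`t = r sqrt((n-2)/(1-r^2))` with n − 2 degrees of freedom, where n is the
channel count — the only per-pair sample size that exists, since each
correlation is taken across channels. It is cross-checked in the tests
against numerical quadrature of the hand-written t density to 1e-8.

Further conventions: the self pair (r = 1, p = 0) is stored and returned —
the query region showing up among its own results is informative, and a
flag (`include_self = FALSE`) drops it; both directions of each unordered
pair are stored so any query row is an O(1) lookup; windows whose feature
vector is constant across channels have undefined correlation and are
excluded from the mask entirely, themselves included; the dense r matrix is
retained alongside the runs while W is below a configurable cap, as raw
correlations are useful programmatically.

A query is (start, length). The length resolves the timescale: the largest
indexed duration that is at most the query length (600 ms resolves to the
500 ms scale); lengths below the smallest duration clamp to the smallest,
where the rule is otherwise undefined. The start resolves the query window
by floor division, boundaries belonging to the window that starts there.
Hits decode into grid-aligned half-open intervals with their p-values.

## Synthetic recordings

`simulate_recording()` emulates a block-design stimulation experiment: by
default 32 channels at 1000 Hz, 48 blocks of 1.5 s alternating two stimulus
conditions. Each channel carries a 1/f-shaped Gaussian background (white
noise whose Fourier amplitudes are scaled by 1/sqrt(f), rescaled to unit
SD) — spectrally realistic enough to load the gamma band with noise without
modeling biophysics. During a condition's blocks, that condition's channel
subset additionally receives a sinusoid whose frequency jitters per block
inside 60–100 Hz, with per-channel random phase and a fixed per-channel
gain in [0.75, 1.25], at amplitude 2. Condition subsets are overlapping
halves of the array (channels 1–16 vs 9–24 under the defaults), so
retrieval cannot succeed by trivially disjoint support. The whole stream is
a deterministic function of one seed, and the generator emits a fully valid
format file (ECoG group + labelled stimulus group).

What this emulates: condition-specific spatial patterns of high-gamma
power over a realistic spectral background, with exact ground-truth labels
(each window is labelled by the block containing its midpoint). What it
does not emulate: line noise and movement artifacts, non-stationary
background, volume conduction, trial-to-trial amplitude drift, or any real
electrode geometry. Passing the retrieval tests therefore shows the
pipeline recovers planted task structure through 1/f noise — not that it
would reach the same AUC on any particular animal's recording.

## Retrieval validation

`evaluate_retrieval()` treats every window in turn as a query: its
correlations with all other windows are thresholded over a fixed common
grid (r from −1 to 1 in steps of 0.01), windows sharing the query's block
label are the actual positives, and TP/FP/TN/FN follow the standard
definitions TPR = TP/(TP+FN), FPR = FP/(FP+TN). The self window is excluded
(its r = 1 would inflate TPR for free); queries with no positive or no
negative candidates are skipped. Rates are averaged across queries per
threshold — with a per-query threshold sweep, threshold-wise averaging is
the one convention that keeps the average well-defined — and the AUC is the
trapezoid over the averaged points with (0,0) and (1,1) appended. An
independent ROC implementation (pROC) is used in the tests purely as an
oracle on single-query sweeps, agreeing within 0.01 AUC.

On the default synthetic configuration the averaged AUC is far above the
99th percentile of a 200-replicate shuffled-label null, and with the noise
amplitude at zero it is exactly 1.0: within-condition feature vectors are
near-identical while overlapping subsets push cross-condition correlations
negative after z-scoring, so a single global threshold separates every
query.

## Problem sizes and budgets

The test suite works at deliberately small scale, chosen so the full
pipeline — format round trips, oracle comparisons, a 200-replicate
permutation null on the 48-window default simulation, and a 200-window,
64-channel null calibration of the index — completes in about a minute on
one core. These sizes are the package's own testing choices; every
operation runs unchanged on hour-long recordings, where indexing cost is
dominated by the one-off all-pairs correlation per timescale.

## Known limitations

* Features are high-gamma band power only; that suits ECoG much better than
  EEG, where band-limited noise can dominate.
* Search is within-file; cross-file or cross-modality (e.g. MNI-space fMRI)
  comparison is out of scope.
* The significance threshold is uncorrected by design, so at alpha = 0.05
  about 2.5% of null pairs (positive tail) enter the index — the null
  calibration test pins this mass.
* The four timescales are a fixed design point; `spectral_config()` exposes
  them, but nothing adapts them to the data.
* The CLI recomputes features/indices on each invocation rather than
  caching sidecars by content hash; for repeated interactive use, keep the
  sidecar files written by `write_features()`/`write_index()`.
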