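---
title: "The correspondence model behind mbralign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The correspondence model behind mbralign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model the package fits, the choices
made where the method leaves room, what the synthetic-data generator does
and does not emulate, and the numerical details a user should know before
trusting the output on their own data.

## The problem and the model

A *feature* is the elution peak of one charge variant of a peptide inside
an extracted-ion chromatogram (XIC). When the same peptide is identified by
Tandem MS in run Q1 but not in run Q2, its Q2 peak must be found among the
several peaks that survive retention-time alignment — warping corrects only
the *mean* elution-time shift, while the residual shift is random. The
matcher therefore scores every candidate pair with two statistics assumed
independent:

* the residual shift $\Delta t = t_2 - w(t_1)$ between the peak apexes
  after applying the warp $w$, modelled for corresponding features as
  $\Delta t \sim N(\mu, \sigma^2)$, with $(\mu,\sigma)$ the sample mean and
  the unbiased ($n-1$) standard deviation of the training shifts;
* the shape dissimilarity $X = 1 - R^2$, where $R^2$ comes from regressing
  the resampled Q2 peak trace on the resampled Q1 trace, modelled as
  $X \sim \mathrm{Gamma}(k, \theta)$, with $(k,\theta)$ the maximum-likelihood
  estimates on the training pairs.

The reported correspondence is the candidate maximising the product of the
two density values. Densities are multiplied unnormalised, exactly as a
likelihood; no posterior calibration across candidates is attempted, so the
score ranks candidates but is not a match probability.

Both model families are deliberately simple. The Gaussian is a reasonable
description of residual shifts once the smooth trend is removed; the Gamma
captures a distribution concentrated near zero with a right tail, which is
what shape dissimilarities of genuinely corresponding peaks look like. The
independence assumption rests on the different physical origins of the two
statistics: residual shifts come from run-to-run chromatographic
fluctuation, shape from the peptide's interaction with the column.

## Training data

The ground-truth list is the intersection of the two runs' identification
tables on the (sequence, charge) key, after per-run deduplication (highest
probability wins, earlier retention time on ties) and a probability filter
(default 0.95). No retention-time filtering is applied to this list — an RT
filter would bias the training shifts toward zero and understate $\sigma$.
The filter threshold also bounds achievable testing accuracy: at 0.95,
about 5% of "truth" entries may themselves be wrong.

The top 20% of entries by Q1 apex intensity form the training set (intense
features are least corrupted by noise); ties are broken lexicographically
so splits are reproducible. Around 200 training pairs are comfortable;
below ~50 the package warns. The Q1 apex intensity is used for the ranking
(rather than Q2 apex or peak area) because the Q1 feature is the one whose
identity is certain; the choice is config-switchable in spirit but fixed in
code for determinism.

Non-corresponding (decoy) pairs are built by replacing the true Q2 feature
of a training pair with a uniformly random *other* detected interval from
the same XIC. These decoys train nothing; they feed the ROC diagnostics and
the separation statistics reported by `summary()`.

## Pre-processing choices

* **XIC window**: ±10 ppm of the target m/z, summed per scan, one point per
  MS1 scan (missing matches contribute zero).
* **Detection trace**: the first-isotope (mono + 1.0033548/z) XIC by
  default. The mono trace can be polluted by co-eluting material one
  neutron below; `detection_trace` can be set to `"mono"` or `"sum"`.
* **Noise**: level = median of the trace; sigma = 1.4826 × the median
  absolute deviation from that level, computed over points at or below the
  90th intensity percentile so the peaks themselves do not inflate the
  estimate. On a pure Gaussian baseline this truncation biases sigma low by
  roughly 10%; on realistic traces (baseline plus sparse peaks) it is
  accurate, and the detection threshold is deliberately conservative.
* **Intervals**: maximal scan runs above level + 3·sigma; runs shorter
  than `min_peak_points = 3` scans are discarded as spikes; at most
  `max_candidates = 20` intervals are kept (highest apexes first). An
  identified feature is the interval containing the recorded RT, falling
  back to the nearest apex within `rt_tolerance_sec = 60`; otherwise the
  peptide is dropped with a warning.

## The shape statistic in detail

The two traces of a pair generally have different lengths and time
supports. Each is linearly interpolated onto `ar_grid_points = 50` equally
spaced points spanning *its own* detected interval. This boundary-to-
boundary alignment decouples the shape comparison from the time shift (the
shift is already measured by $\Delta t$) — but it also normalises peak
*width* away, so discrimination rests on asymmetry, shoulders and fine
structure. Consequently two clean, featureless Gaussian peaks of different
widths look nearly identical to this statistic; it earns its keep on real
chromatograms, whose peaks carry tails and shoulder structure. The
synthetic generator plants exactly such structure (see below).

$R^2$ of a simple linear regression equals the squared Pearson correlation
of the two resampled vectors, which is how it is computed; it is clamped to
[0, 1] and a zero-variance trace yields 0 with a warning. Before the Gamma
fit, $x = 1 - R^2$ is clamped below at `x_floor = 1e-6`: on clean data many
training pairs reach $R^2 = 1$ and an unclamped MLE would chase a density
spike at zero.

## Warping

The warp is a least-squares polynomial (default degree 3) from Q1 to Q2
time, fitted on the training pairs' apex times. Degree 3 follows the
observation that real inter-run warps are smooth and mildly non-linear; the
fit is by QR, with automatic degree reduction on rank deficiency. One
numerical guard matters: a cubic fitted on very few points whose time span
does not cover the gradient extrapolates catastrophically. The effective
degree is therefore capped at one coefficient per ~5 training pairs, so
small training sets fall back toward a robust linear warp. Extrapolation
beyond the training domain is permitted (and noted in messages) — matching
must still work for peptides eluting outside the training span.

## Multi-run propagation

For ≥3 runs, models are trained once per unordered run pair on their shared
identifications; the reverse direction reuses the same training features
with the warp refitted backwards and the Gaussian refitted on the reversed
residuals (the Gamma shape model is direction-free). For each peptide in
the union set and each run where it lacks an identity, source runs are
tried in order: Tandem-MS-identified sources by descending probability,
then already-propagated sources, then run order. Passes repeat until no new
interval is located, so identities can hop through an intermediate run.
When two sources disagree, the higher-probability source has already won by
construction of the order. The coverage report exposes two denominators —
the union minus the full intersection (the set propagation can act on) and
the full union — because either convention is defensible.

## The synthetic generator

`sim_config()`/`simulate_runs()` emulate the statistical structure the
matcher assumes, with every quantity reproducible from one seed:

* per-peptide elution profiles from an exponentially-modified-Gaussian
  family plus a random *shoulder* component (second EMG at a small offset
  with its own width/tail). The shoulder is what gives different peptides
  visibly different shapes under boundary-to-boundary resampling; a pure
  two-parameter EMG family would make all peaks near-identical to the
  shape statistic. A clean single-Gaussian family is available for
  analytic checks;
* a smooth non-linear warp per run (identity for run 1), plus Gaussian
  apex jitter `at_sigma` (default 3 s) in every run;
* per-run shape perturbation (relative width/tail jitter `shape_noise`,
  default 0.08, plus mild multiplicative trace noise), so 1 − R² of
  corresponding pairs concentrates near zero with a right tail;
  `shape_reproducible = FALSE` draws independent shapes per run,
  destroying the shape signal on purpose;
* interfering decoy peaks in the same m/z window (default 3 per peptide at
  30–90 s offsets — resolved from the true peak; `sim_config_crowded()`
  plants 2 decoys within ±3·at_sigma of the apex with narrow peaks, the
  regime where warping alone is ambiguous);
* log-uniform per-run intensity scaling (ratios up to 50× by default),
  Gaussian baseline noise on every trace point, and identification tables
  sampled per run (`identified_fraction`) with Beta-distributed
  probabilities.

Planted false positives (`id_false_positive_rate`, per run) re-point an
emitted identification's RT at an interfering peak and draw their
probability from the same high Beta as true identifications: they model
the confidently-wrong identifications that a probability filter cannot
remove, which is the regime in which accuracy is ceiling-bounded by the
contamination rate. Low-confidence false positives would simply be
filtered out and exercise nothing.

The generator does **not** emulate: profile-mode data, isotope envelopes
beyond the mono and first-isotope traces, MS2 spectra, charge-state or
labelling structure, intensity-dependent mass error, or systematic
(non-smooth) retention drift. Passing tests on this generator therefore
demonstrates the statistical machinery — warp estimation, density fitting,
likelihood ranking, propagation bookkeeping — not robustness to every
artefact of raw instrument data.

## Problem sizes and tolerances used in the tests

The test suite fits the default benchmark at 150 peptides × ~900 scans per
run, the crowded benchmark at 150 peptides × 1750 scans (20 seeds for the
shape-gain comparison, 12 for the shape-destroyed regime), a 400-peptide
panel for the false-positive sweep (where a handful of corrupt training
pairs must be dilutable, as they are at realistic training sizes), and a
200-peptide, 3-run panel at 50% identification for coverage. Monte-Carlo
parameter-recovery checks use 270 training pairs, a realistic shared-
identification count for a run pair. These sizes keep the full suite to a
few minutes while leaving every comparison comfortably outside its
tolerance under the fixed test seeds.

## Known limitations

* The score is a ranking device; it carries no false-discovery control.
  A peptide with no detectable Q2 peak is reported unmatched, but a
  peptide whose true peak is missing while a decoy is present will be
  matched to the decoy with a (typically low) score.
* Heavily overlapping peaks merge into one detected interval at the
  noise-based threshold; the matcher then scores the merged composite.
  Mixture deconvolution is out of scope.
* The Gaussian shift model is not robust to gross outliers in the training
  set; the probability threshold is the intended control for
  identification contamination.
* `compute`-time scales linearly in peptides × scans; all loops are plain
  R and comfortable at the tens-of-thousands-of-XICs scale, but a full
  proteome-scale run pair will take minutes, not seconds.
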