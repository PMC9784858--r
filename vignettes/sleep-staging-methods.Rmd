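---
title: "Methods: cascaded SVM sleep staging from single-channel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded SVM sleep staging from single-channel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcascade)
```

## The problem

Sleep is scored in 30-second epochs into five stages — wake (W), the three
NREM stages N1–N3, and REM (R) — conventionally from full polysomnography.
`sleepcascade` implements an automatic stager that needs only a single EEG
channel sampled at 100 Hz (3000 samples per epoch), the setting of wearable
monitors. The pipeline is: wavelet threshold denoising, wavelet packet band
extraction, a 51-feature description of each epoch, mutual-information-based
feature ranking, and a two-stage ("cascaded") one-vs-one SVM classifier.
Stage N1 is the notorious weak point of single-channel staging — it is rare
(about 7% of a night) and spectrally intermediate between wake, N2 and REM —
and most of the design choices below exist to protect it.

## Preprocessing

**Denoising.** Each epoch is decomposed to 7 levels with the db8 discrete
wavelet transform and detail coefficients are soft-thresholded. The noise
scale is estimated once from the finest detail level, `sigma =
median(|d1|)/0.6745`, because for band-limited signals that level is almost
pure noise; estimating per level would let levels that carry genuine
rhythms inflate their own threshold and delete them. The threshold itself
is chosen per level by the hybrid SURE rule: a level whose coefficients
look like pure noise receives the universal threshold
`sigma*sqrt(2*log(N))`, while a level dense with signal receives the
threshold minimising Stein's unbiased risk estimate, which is typically
much smaller. Plain soft universal shrinkage is a poor default here: on a
dense oscillation its shrinkage bias exceeds the noise it removes at any
noise level, so denoising would make epochs *worse*. The `threshold_rule`
argument exposes `"universal"` and `"universal_by_level"` for comparison
and `"none"` for a pure transform round trip.

**Band extraction.** A 7-level wavelet packet transform tiles the 0–50 Hz
axis into 128 bands of 50/128 = 0.390625 Hz. Terminal nodes are reordered
by the Gray-code (sequency) permutation — the natural tree order is not
monotone in frequency because decimating a highpass branch mirrors its
spectrum — and each characteristic wave is reconstructed from every node
whose interval overlaps its band with positive measure: alpha 8–13 Hz,
beta 12–30, theta 4–8, delta 0.5–2, spindle 12–14, sawtooth 2–6 Hz. The
1 Hz K-complex rhythm lies inside the delta band and is not reconstructed
separately. Two numerical facts matter for interpretation:

* Reconstructions over any node-aligned tiling sum back to the input to
  machine precision (the transform is orthogonal; epochs are
  reflect-padded from 3000 to 3072 samples and truncated after inversion,
  which preserves this identity exactly).
* Deep wavelet packets built from 16-tap filters have side lobes: a pure
  tone's own band captures roughly 87–99% of its energy depending on
  where the tone falls within a node, the rest leaking to neighbouring
  and aliased bands. This matches reference wavelet-packet
  implementations and is inherent to the transform, so tests assert
  dominance of the correct band rather than an idealised capture figure.

## The 51-feature system

Per epoch, on the denoised signal and its six reconstructed waves:

| group | features |
|---|---|
| dispersion (6) | per-wave `Std`, the *unnormalised* root sum of squared deviations (the conventional estimator is available via `conventional = TRUE`) |
| auxiliary time domain (17) | mean, median, variance, mean absolute value, RMS, peak-to-peak, skewness, kurtosis, zero crossings, Hjorth activity/mobility/complexity, line length, IQR, 75th percentile, min, max |
| energy (8) | per-wave `sum(w^2)` plus the alpha/theta and delta/theta energy ratios, aimed at the N1-vs-R and N1-vs-N2 confusions |
| frequency (9) | per-wave periodogram power, the spectral centroid (MNF) of the epoch, and the alpha/theta, delta/theta power ratios |
| Renyi entropy (6) | order 2 (`-log(sum(p^2))`, natural log) of each wave's normalised spectrum |
| nonlinear (5) | Lempel–Ziv complexity, multi-scale entropy, spectral entropy, sample entropy, fuzzy entropy |

Notes on the less standard choices:

* **Std without 1/n** is kept literally as the feature system defines it;
  under the per-model standardization it is equivalent to the conventional
  estimator anyway (a fixed scalar multiple).
* **LZC** uses the 1976 exhaustive-history parse of the median-binarised
  epoch and is reported as `c(n) * log2(n) / n` so the value is comparable
  across lengths; the raw phrase count is available with
  `normalize = FALSE`.
* **Multi-scale entropy** is sample entropy (m = 2, r = 0.2 SD of the
  *original* epoch) of the coarse-grained series at scale tau = 11. A
  literal per-point summation over the coarse series would just multiply
  this by the number of coarse points at fixed tau; that variant sits
  behind `literal_sum = TRUE`.
* **Sample/fuzzy entropy** are the Richman–Moorman and
  exponential-membership (gradient 2, mean-subtracted templates)
  definitions, computed in C++ and verified against brute-force counting
  oracles to 1e-9.
* Degenerate epochs fail loudly: a constant epoch has r = 0.2·SD = 0 and
  sample entropy is undefined; a zero theta band makes the ratios
  undefined. Such epochs abort with the epoch index in the message rather
  than propagating NaN.

## Feature ranking

Features are ranked once by the mutual-information quotient: relevance to
the stage label divided by mean redundancy against the other 50 features,
`MIQ(f) = I(f, g) / ((1/|F|) * sum_{f' != f} I(f, f'))`, all MIs computed
as plug-in estimates (natural log) on discretized columns. This is the
one-shot quotient form, not the incremental greedy variant: every feature
is scored against the full set and sorted. Discretization is rank-based
quantile binning into 10 bins — codes depend only on ranks, so monotone
transforms leave them unchanged, ties share a bin, and binary features
survive intact. A feature empirically independent of all others (zero
redundancy) is ranked above quotient-ranked ones by relevance, with a
warning. In every evaluation protocol the ranking is computed on training
rows only, so no information about held-out epochs leaks into feature
choice. The stage-I classifier uses the top 32 features, stage II the top
30; accuracy plateaus near those sizes.

## The cascaded classifier

Columns are standardized with *population* mean and SD fitted on training
rows and reused unchanged at prediction. Binary machines use the
homogeneous quadratic kernel `(x.z)^2` with the soft-margin dual solved by
libsvm (via e1071); support vectors, multipliers, and bias are stored so
every decision value is a direct kernel summation, with `u >= 0` mapping
to the positive class. The dual solution satisfies the KKT conditions (box
constraint, `sum(alpha*y) = 0`) to 1e-6, which the tests assert.

One caveat of that kernel worth knowing: it is even, `k(-x, z) = k(x, z)`,
so classes that differ only by sign of their coordinates are
*inseparable*; separation must come from the magnitude structure of the
standardized features. Toy examples in the tests are therefore built on
radius-separated clusters.

Multi-class decisions are one-vs-one: three machines for a 3-class
problem, each casting one vote, ties broken by the larger summed absolute
decision value among the tied classes, then canonical order. The cascade:

1. **Stage I** classifies W / REM-LS / N3, where REM-LS merges {R, N1,
   N2} — the triad that actually gets confused. W and N3 decisions are
   final.
2. **Stage II** resolves REM-LS epochs into R / N1 / N2. Its training set
   is rebalanced around N1: every N1 epoch, an equal number of R epochs,
   and twice as many N2 epochs, sampled without replacement under the
   model seed. On a night-proportioned dataset this converts a 7% N1
   share into 25%, which is what rescues N1 recall; on an artificially
   balanced dataset the rule degenerates to taking everything available
   (with a warning) and the cascade's remaining advantage is only
   structural. A 10-fold cross-validation accuracy on the rebalanced
   subset is reported as a training diagnostic, after which stage II is
   refit on the whole subset.

`Const` (the box constraint C) defaults to 1 and is deliberately not
tuned per fit; the only tuning hook is the stage-II CV diagnostic.

## Evaluation

`confusion_and_metrics()` builds the 5x5 true-by-predicted table;
accuracy is trace over total, precision is per predicted column, recall
per true row, and empty margins yield `NA` rather than 0.
`repeated_holdout()` runs the 90/10 protocol five times by default:
stratified splits (keeping rare N1 in both halves), training-only
ranking, and per-repeat metrics with mean and SD. Everything is
bit-for-bit reproducible from the protocol seed: repeat i derives its
split, subsample and fold seeds from `seed + i`.

`topsis_scores()` compares feature-subset candidates on (computing time,
overall accuracy, N1 accuracy): min-max normalisation with time as a
cost, ideal/anti-ideal at the normalised extremes, weighted Euclidean
distances *with* the square root (the standard TOPSIS form; the
no-root variant is available via `sqrt_distance = FALSE`), and score
`D- / (D+ + D-)`. Equal weights are the default. A criterion with no
spread is dropped with a warning since it cannot discriminate.

## The synthetic generator

Real overnight recordings cannot ship with a package, so every test runs
on generated epochs. The generator emulates the *spectral* structure that
the feature system is built to detect, over 1/f background noise of unit
SD: continuous alpha+beta for W, high-amplitude delta for N3, and a shared
low-voltage theta background for the N1/N2/R triad that differs only
through transient events — sparse 13 Hz spindle bursts and K-complex-like
transients for N2 (Poisson counts, occasionally absent entirely),
sawtooth-shaped 4 Hz bursts for R, and an occasional leftover alpha
fragment for N1. Amplitudes get per-epoch log-normal jitter and
frequencies ±5% jitter. This makes the triad overlap the way it does in
real data, with N1 hardest, while W and N3 stay easy.

The single `separation` knob scales all oscillation amplitudes. The
default, 1.25, puts the stages in an easy regime: the end-to-end tests
are meant to verify the *mechanics* of the pipeline (feature extraction,
ranking, training, routing) rather than clinical difficulty, and at this
setting the five-repeat holdout recovers stages with high accuracy.
`separation = 1` is the realistic-hardness setting: noticeably lower
overall accuracy with N1 clearly the weakest stage and the N1/N2/R triad
supplying most of the confusion.

What passing these tests does **not** show: robustness to artifacts,
inter-subject variability, electrode drift, non-stationarity within
epochs, or the true morphology of spindles and K-complexes. The generator
produces stationary band-limited processes; real EEG is none of that.

## Problem sizes and runtime choices

The end-to-end study uses 200 epochs per stage (1000 epochs, 8.3 hours of
signal) with five 90/10 holdouts — large enough for stable accuracy
estimates while keeping the dominant cost, the O(n^2) fuzzy-entropy scan
of each 3000-sample epoch, to a few minutes for the whole table. Entropy
kernels are C++; everything else is vectorised R. Oracle comparisons in
the tests use series of at most 200 samples where brute force is exact
and instant.

## Known limitations

* The EDF reader handles the plain EDF subset used by the common public
  sleep corpora (identical record layout, 16-bit samples); EDF+
  annotation streams are read from plain-text onset/duration/label CSVs
  instead of embedded TAL blocks.
* Band reconstructions inherit wavelet packet side lobes (above); band
  powers are therefore estimates, not brick-wall filters.
* The cascade's N1 advantage is a property of imbalanced data; on
  balanced training sets the rebalancing rule is inert by construction.
* `Const`, the bin count, and the top-k sizes are fixed defaults, not
  per-dataset tuned values; the config surface exposes them all.
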