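---
title: "Cross-day calibration and consensus feature selection for EEG emotion decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-day calibration and consensus feature selection for EEG emotion decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdays)
```

## The problem

An emotion classifier trained on one day's EEG often fails on another
day's: band-power features carry day-specific offsets (electrode
placement, impedance, baseline physiological state) alongside the
emotion-related signal, and a classifier fit to a single session learns
both. `eegdays` implements, as a reusable and fully tested pipeline,
the standard toolkit for quantifying this effect and for mitigating it
by *pooling training data across days*:

* **WDC** (within-day classification): train and test inside one day —
  an optimistic upper bound untouched by drift.
* **SCDC** (standard cross-day classification): train on one day, test
  on each other day — the pessimistic deployment scenario.
* **LNDI** (learning-N-days information): train on samples pooled
  equally from N of the 5 days, test on the held-out 5−N days, averaged
  over all $\binom{5}{N}$ day combinations and 10 re-randomizations.
* A **window-width** analysis that alternates temporally consecutive
  blocks between train and test inside a day, exposing slow within-day
  drift.
* A **modified recursive feature elimination** that ranks features per
  day-fold by the accuracy loss their removal causes, takes each fold's
  top-M list, and keeps features appearing in at least 3 of the 5 lists
  (the *salient subset*), validated on a held-back half of the data.

Because the recordings this protocol family was developed on are not
publicly deposited, the package ships a synthetic multi-day generator that emulates
the recording setup (60 channels, 6 bands, 5-s epochs at 500 Hz, 5
days, 3 classes, unequal day sizes) at both the raw-signal and the
feature level, so every downstream stage is testable end to end.

## The generative model

Both generators draw from one log-linear band-power model. For epoch
$e$ of class $l$ on day $d$, channel $c$ and band $b$:

$$\log_{10} P_{e,l,d,c,b} = \beta_{c,b} + \gamma_{l,c,b} + \delta_{d,c,b}
  + \eta_{d,c,b}\,t_e + \varepsilon,\qquad
  \varepsilon \sim \mathcal N(0, \sigma^2)$$

* $\beta$ — baseline log10 band power; the default per-band profile
  (1.5, 1.0, 1.1, 0.7, 0.2, 0.0 for delta…high gamma) follows the
  1/f-like decay of resting EEG with the usual alpha bump, in µV²
  units.
* $\gamma$ — class effect, nonzero only on a sparse informative set of
  (channel, band) pairs and *zero-mean over classes* per pair, so class
  priors never leak through marginal shifts. Each informative pair
  receives a distinct zero-mean direction over the 3 classes (equally
  spaced unit vectors in the 2-D zero-sum plane, scaled to the norm of
  the reference pattern $(1, 0, -1)$): informative features carry
  complementary, not duplicated, class information. The default set is
  8 pairs biased to the gamma bands, mirroring the gamma dominance
  commonly reported for emotion-discriminative features.
* $\delta$ — day offsets, drawn $\mathcal N(0, \sigma_{day}^2)$ *fresh
  per realization* so Monte-Carlo properties average over drift
  configurations; a fixed-$\delta$ mode supports regression tests. The
  offsets can be confined to non-informative pairs
  (`day_effect_on = "noninformative"`) or given a separate scale on the
  informative set (`day_sd_informative`), because day-dependent and
  emotion-related features need not drift equally.
* $\eta\,t_e$ — optional slow within-day drift: a per-(day, channel,
  band) linear slope over the epoch's temporal position. Each class is
  treated as a parallel stream spanning the session (positions are
  computed within class), sharing the day's drift profile. This
  matters: if classes occupied sequential temporal blocks instead,
  within-day drift would become a class confound and *improve*
  apparent accuracy with window width rather than degrade it.
* $\varepsilon$ — i.i.d. per-(epoch, channel, band) log-power noise.

Powers are returned on the linear scale ($10^x$). Log10 rather than
natural log is cosmetic (band-power figures are conventionally log10);
either is internally consistent.

The signal-level generator synthesizes each channel as a sum over
bands of band-limited Gaussian noise, built by frequency-domain
masking of white noise — exact band confinement, unlike FIR filtering,
which makes the spectral oracle exact — and scaled so the *realized*
band power equals the target drawn from the model (a strictly stronger
guarantee than matching in expectation; it makes the Monte-Carlo
band-power checks robust at small epoch counts). Optional mastoid
channels carry a shared common-mode signal for exercising
re-referencing. The generator deliberately omits ocular/muscle
artifacts, volume conduction and inter-channel correlation beyond the
common mode: a green test establishes the *procedures*, not realism of
the worlds.

## Feature extraction

Welch's method with 500-ms Hamming segments at 50% overlap (19
segments per 5-s epoch), each segment mean-detrended; band power is
the *integral* of one-sided spectral density over half-open
$[f_{low}, f_{high})$ intervals, left edge inclusive, so the shared
edges 4, 8, 13, 30, 44 Hz are assigned uniquely and the six bands
approximately tile total power on $[0.5, 100)$ Hz. 60 channels × 6
bands give the canonical 360 features, channel-major, named
`CH{i}_{band}`.

Two numerical caveats the tests encode explicitly:

* With 500-ms segments the frequency resolution is 2 Hz and a Hamming
  window retains only ~73% of a tone's power in its exact bin (~13% in
  each neighbour). Band powers therefore match a full-epoch
  periodogram oracle within 5% only for tones whose ±1-bin
  neighbourhood stays inside the band; the delta and theta bands are
  one to two bins wide and *cannot* meet that bound at their edges with
  the stated segmentation — no faithful implementation can. Total
  power (Parseval level) agrees within 5% for tones from 4 Hz (two
  cycles per segment) upward; slower tones are additionally biased by
  the segment-mean detrend, which removes real sub-2-Hz signal
  (measured: −14% at 2 Hz, +20% near 3 Hz). The same physics biases
  Welch band power of broadband signals in the two lowest bands
  (delta ≈ 0.5×, theta ≈ 1.65× their true values on the default
  baseline spectrum), which is why the generator's band-power checks
  use the full-epoch periodogram — exact by construction — as the
  oracle, and reserve Welch agreement for the four bands its
  resolution can represent.
* The high-gamma edge is capped at 100 Hz exclusive, comfortably below
  the 250-Hz Nyquist of 500-Hz data.

Preprocessing: re-referencing subtracts the mean of named reference
channels (bilateral mastoid convention) and drops them; decimation
applies an exact frequency-domain anti-alias low-pass at the new
Nyquist before keeping every k-th sample (integer ratios only). An
artifact-removal hook exists but defaults to the identity — synthetic
epochs carry no ocular artifacts.

## The classifier

The protocols need a deterministic, pluggable multiclass backend. The
default is a radial-basis-kernel regularized least-squares classifier
with one-vs-one voting — a soft-margin-style kernel machine standing
in for a library SVM, which is not available in the supported
dependency set. Configuration (all recorded in result provenance):

* `cost` (default 1): ridge penalty is `1/cost`.
* `gamma` (default): the variance-scaled width rule
  `1 / (p · mean feature variance)` on the standardized training set.
* `standardize` (default on): z-scoring by *training* statistics only,
  applied to both sets — band powers span orders of magnitude across
  bands and kernel machines are scale-sensitive.
* `transform` (default `"log10"`): band powers are log-normal by
  construction and the log is the field's variance stabilizer; raw
  linear powers measurably hurt every backend (within-day accuracy
  ~0.95 instead of ~1.0 on cleanly separable worlds). Inputs that can
  be non-positive require `transform = "none"`.
* Voting ties break toward the earlier class in training order;
  backends `"linear"` and `"centroid"` are injectable for sensitivity
  analyses.

All backends are deterministic given config and inputs, invariant to
training-row permutation and to common positive rescaling of the
features.

## Protocols and the sample budget

The budget rule $M_{min} = \lfloor \min_i M_i / 12\rfloor \times 12$
makes the per-day training quota $M_{min}/N$ and testing quota
$M_{min}/(5-N)$ integral for every $N \in \{1..4\}$. One subtlety: the
*per-class* quota $M_{min}/(3N)$ is **not** always integral (N = 3
gives $M_{min}/9$, and divisibility by 12 does not imply divisibility
by 9); quotas are therefore split over the 3 classes as evenly as
possible, the remainder going to the first classes in sorted label
order — deterministic and at most one row apart.

WDC performs 5 repetitions of a class-stratified random 80/20 split
per day; SCDC trains on a stratified 80% draw of one day and tests on
*all* rows of each other day (the two conventions — budgeted LNDI test
sets, exhaustive SCDC test sets — are both deliberate, matching the
conventions they were defined with). WDC and SCDC training draws are capped at a common
row count (the smallest 80% pool over days) so their comparison is
fair. LNDI runs 10 repetitions over all $\binom{5}{N}$ combinations.
Every (repetition, combination) cell derives its own child seed from
the master seed by a documented mixing function, so any single cell is
reproducible in isolation; repetitions re-randomize the row
subsampling (the built-in backends have no internal randomness to
re-seed).

The window-width analysis alternates consecutive blocks (1, 12, 60
epochs, or half the session) between train and test within each day
and class, starting with train, and involves no randomness at all.

## Feature selection

Per held-out day (5 folds on the selection half of a 50/50
day-stratified split): iteratively remove each surviving feature once,
score the remaining set on the budgeted test draw of the held-out day,
eliminate the feature whose removal leaves the highest accuracy
(minimum loss; ties eliminate the lowest feature index —
deterministic, seed-independent), and recurse to exhaustion. The last
M eliminated form the fold's top list; features on ≥ 3 of the 5 lists
are the salient subset, validated on the untouched half under
L1DI–L4DI with identical seeds for the all-features and subset runs
(paired comparison). A `step = k` mode eliminates k features per round
and `stop_at` floors the recursion, for tractability at full 360-D;
the test suite runs at ≤ 42 features. M defaults to 100 (the reported
choice at 360 features) but is exposed because the nominal M, the
rule "top M", and the reported mean subset size of the reference
analysis are mutually irreconcilable; the realized subset size is always reported. For the
40-feature test beds we use M = 20, matching the realized
subset-to-feature ratio (~174/360) rather than the nominal M.

### Limits of accuracy-loss ranking (an honest negative)

The recovery criterion — the consensus subset should capture ≥ 80% of
8 planted informative features among 40 in ≥ 8 of 10 seeds — stays
**red**, deliberately. With the stated per-feature signal (class
effect 0.5, noise 0.2), two regimes exhaust the design space:

* Without day drift on the informative features, every fold classifier
  saturates at accuracy 1.0; leave-one-out accuracy loss is then zero
  for *every* feature, elimination order degenerates into the
  deterministic tie-break, and top lists are arbitrary.
* With enough drift to de-saturate (the committed recovery world uses
  `day_sd = 1.0` on all features, placing fold accuracy near the
  0.6 regime typical of cross-day emotion decoding), individual informative
  features genuinely lose their class signal on roughly a third of
  held-out days, so the 3-of-5 consensus drops 2–4 of the 8.

Measured recovery across drift placements (uniform, nuisance-only,
asymmetric), M ∈ {12, 16, 20}, budgets M_min ∈ {12, 36, 60}, backends
(RBF, centroid) and regularization settings never exceeded ~5–7 of 8.
This is the classic redundancy-masking weakness of wrapper rankings
that score features by marginal accuracy loss — redundant informative
features shield each other — and not an implementation defect; the
single-informative-feature recovery test passes 10/10. Relatedly, the
consensus subset does not outperform the full feature set under
nuisance-only drift (the ranking that produced it was
saturation-degenerate there); the *known* informative subset does,
decisively, which is what the subset-validation criterion checks.

## Synthetic worlds used by the acceptance tests

Drift magnitudes have no empirical anchor (no distributional
description of real inter-day drift is available), so the presets fix
them once, qualitatively, to land in the regimes the protocols were designed to expose: `preset_chance` (no class effect — chance floor),
`preset_separable` (effect 2.0, no drift — saturation ceiling),
`preset_strong_drift` (effect 0.6, day_sd 0.6 — within-day high,
cross-day collapsed), `preset_moderate_drift` (effect 0.35, day_sd
0.3 — the regime where each added training day pays),
`preset_within_day_drift` (slope sd 2 against effect 0.3 — monotone
degradation over block widths), `preset_noise_drift` and
`preset_rfe_recovery` as above. Day sizes are unequal by default
(e.g. 30/40/34/36/44 per class per day, M_min = 84 for the full-size
model), exercising the floor rule. What a green acceptance test
establishes is that the *procedures* produce the qualitative phenomena
they were designed to expose on worlds stated in advance — not that
the worlds resemble any particular laboratory's recordings.

## Reporting

Confusion matrices follow the predicted-row / true-column convention
with row normalization. Paired accuracy comparisons use the paired t
statistic with two documented degenerate conventions: identical
vectors give t = 0, p = 1; a nonzero constant difference reports an
infinite statistic with p = 0 and a `degenerate` flag. All result
files are tidy delimited text with a JSON sidecar embedding the
configuration and its content hash; `eegdays_cli()` exposes simulate /
extract / evaluate / select / validate / report subcommands over the
same machinery.

## Known limitations

* The RBF kernel ridge stand-in is not a maximum-margin SVM; decision
  boundaries can differ near the margin, though every protocol-level
  property tested is backend-agnostic.
* The generator's independence of (channel, band) noise is unrealistic
  (real EEG has strong spectral and spatial correlation); protocols
  are insensitive to this, but absolute accuracies on synthetic worlds
  should not be read as predictions for real data.
* Full recursion on 360 features costs ~65k fits per fold; use
  `step`/`stop_at` or the centroid backend for exploratory runs.
* The recovery criterion discussed above is retained red rather than
  weakened; treat the salient subset as a stability ranking, not an
  oracle for ground-truth informativeness under redundancy.
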