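---
title: "Classifying driving EEG with a Hopfield content-addressable memory"
author: "eegcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driving EEG with a Hopfield content-addressable memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegcam)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, what the synthetic data does and does not
emulate, the tunable parameters, and the numerical and design choices made
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The classification problem

During simulated driving, turning left and turning right are hypothesised
to produce distinguishable scalp EEG signatures. The pipeline asks whether
a content-addressable memory — a Hopfield network storing one bipolar
prototype per class — can recover the turn direction of a 5-second EEG
epoch from its quantitative-EEG profile. The study layout assumed
throughout is a 5-minute session of 4 laps with 4 turns per direction per
lap (32 turn events, 16 per direction), recorded on the 19-channel 10–20
montage at 500 Hz.

Electrode numbering for feature names follows the convention in which the
occipital leads precede the lateral frontal/temporal chain
(FP1, FP2, F3, F4, C3, C4, P3, P4, O1, O2, F7, F8, T3, T4, T5, T6, FZ, CZ,
PZ), so that `"15d"` reads "15th electrode (T5), delta band".

## The Hopfield memory

`hopfield()` stores ±1 patterns by the Hebbian outer-product rule
(`w_ij = Σ_p x_i x_j`, zero diagonal, symmetric, integer weights) and
recalls by iterated sign-threshold updates. Key choices:

* **Tie rule.** `sign(0) = +1` everywhere — in the update rule, in feature
  binarization, and in prototype construction. One global, documented rule
  keeps every stage deterministic.
* **Dynamics.** The default schedule is asynchronous in seeded random
  order, which guarantees energy descent (`E = −½ Σ w_ij x_i x_j + Σ T_i
  x_i` never increases under a single-neuron update); a synchronous mode
  implements the matrix form of the update and is used where a
  deterministic oracle is wanted. Synchronous dynamics can enter 2-cycles;
  recall then reports `converged = FALSE` at the sweep cap.
* **Convergence.** Full-sweep stability, capped at 40 sweeps — the
  iteration budget used in the distortion experiment.
* **Distortion.** `distort()` flips exactly `round(fraction · n)` distinct
  positions (IEEE round-half-to-even; 15% of 6 bits is 1 flip).
* **Two performance readings.** With six patterns in six neurons the
  network is far above the ~0.138·n capacity: stored patterns need not be
  fixed points and recall may land on spurious or neighbouring attractors.
  "Performance" is therefore reported both pattern-level (probe recalled to
  a state uniquely nearest its own source) and bit-level (fraction of
  final-state bits matching the source); the bit-level reading is the one
  consistent with quoting a mean error of `1 − performance`.

## Feature extraction and selection

* **Band powers.** Single-taper periodogram of the whole epoch
  (rectangular window by default, Hann optional), mean removed first,
  normalised so the bin total equals the signal's mean square (Parseval).
  A bin belongs to a band if its centre frequency lies in the closed
  interval `[low, high]`; with the canonical bands (1–3.5, 4–7.5, 8–12,
  12.5–25, 25.5–30 Hz) the closed-edge rule is unambiguous because the
  band edges do not touch. Units are µV² throughout.
* **Ranking.** Welch (unequal-variance) two-sample *t* per feature between
  LEFT and RIGHT epochs, ranked by |t| descending; ties keep column order.
  p-values are reported descriptively and deliberately uncorrected — the
  statistic ranks features, it does not test hypotheses. Features are
  centred but not rescaled before ranking (the *t* statistic is already
  scale-free; an affine rescaling of a feature leaves it unchanged).
* **Two-stage selection.** Channels are ranked by mean |t| over bands and
  bands by mean |t| over channels, and the cross product of the top 7
  channels × top 2 bands (14 features) is kept. Mean aggregation is the
  default because the two dimensions are described as ranked separately;
  max-aggregation is available.
* **Binarization.** Each selected feature is centred by its cross-epoch
  mean; positive → +1. Class prototypes binarize the class means with the
  same centres. A consequence worth knowing: with balanced classes the two
  prototypes are exactly complementary, so constant-position pruning
  (`prune_constant()`) is a no-op on balanced data and matters only for
  unbalanced splits or degenerate features.

## Preprocessing

"Phase-shift free Butterworth band-pass, 12 dB/octave" is read as a
2nd-order Butterworth applied forward–backward (`signal::filtfilt`):
zero-phase, 12 dB/octave per pass, 24 dB/octave effective. The amplitude
screen decomposes each channel at 8 Hz into slow and fast components
(delta+theta vs alpha+beta — the split frequency is a documented choice,
not given with the 50/30 µV thresholds) and rejects an epoch if any
channel's slow peak exceeds 50 µV or fast peak exceeds 30 µV, peak meaning
the maximum absolute sample of the filtered component. ICA artifact
cleaning is a pass-through hook (`ica_hook()`): synthetic sessions are
generated clean or with transients the amplitude screen removes, and
re-implementing Infomax is out of scope.

## The synthetic study

`generate_session()` emulates the statistical structure the analysis
assumes, not the biophysics:

* **Background**: independent Gaussian noise per channel per sample
  (default sd 10 µV), optionally 1/f-shaped. No volume conduction, no
  channel covariance, no real artifact topographies.
* **Events**: evenly spaced within laps, alternating LEFT/RIGHT, with
  seeded jitter (10% of the inter-event slot) — the lap layout is given by
  the study design; exact timings are not, so even spacing is a choice.
* **Turn signatures**: for each turn event matching a group signature, a
  zero-mean sinusoidal burst at the band's centre frequency spans
  `[onset, onset + 5 s]` (the per-turn window length is a free parameter;
  5 s is the package default). The burst amplitude is set so that the
  epoch's power in that band reaches `multiplier ×` the background band
  power (default multiplier 3). Bursts are demeaned because oscillatory
  activity displaces no DC baseline; without this the time-domain baseline
  would inherit spurious information from partial-cycle means.
* **Groups**: three behavioural groups with delta-band signatures — G1
  elevates FP2 and O1 on RIGHT turns; G2 elevates F7 on RIGHT and P3 on
  LEFT; G3 elevates FP2, P3 and T4 on LEFT. The default ten subjects are
  assigned G1: 1, 2, 5, 8, 10; G2: 3, 6; G3: 4, 7, 9.

What passing tests on these data show — and what they do not: the pipeline
recovers planted band-power effects, respects its leakage guards, and
reproduces the qualitative behaviour of the method (selection helps,
individual modelling beats pooling, recall degrades with distortion). They
cannot show that real driving EEG contains such signatures, and real-data
accuracies are not reproduction targets here; the generator has no
within-group inter-subject variability, so the gap between pooled and
per-subject classification is smaller than it would be on heterogeneous
human data.

## Evaluation design

All evaluation flows classify held-out data:

* **Time-domain baseline**: per-class electrode means over the first 50 s
  of turn signal (19 × 25000 samples per class at the defaults) are
  binarized into two prototypes; probes are per-epoch mean vectors of
  epochs *not* consumed by the prototypes. At the default layout only
  5–6 epochs per class remain, so the test set is capped by availability.
* **Band-wise and pooled feature-selected classification**: a seeded
  stratified 70/30 split; centring, pruning, selection and training on the
  training side only. Early-stage experiments in this tradition often
  tested on training-derived patterns; the held-out design is used
  everywhere here because in-sample probes reward noise features (each
  probe has contributed to its own class prototype) and can invert the
  benefit of feature selection.
* **Monte-Carlo cross-validation** (`monte_carlo_cv()`): 10 repeats of
  stratified 70/30 random sub-sampling (with 10 + 10 epochs per class:
  14 train / 6 test), feature selection refit per repeat — the selected-id
  list per repeat depends only on the training split, which the tests
  assert. Splits are clamped so neither side ever loses a class.
* **Significance**: exact binomial tests of pooled test decisions against
  0.5 (and label-permutation checks in the test suite) replace parametric
  ANOVA on accuracies — self-contained and assumption-light at these
  sample sizes.
* **Per-subject pipeline**: epochs surviving the screen are taken
  first-come (10 per class), mirroring a deterministic "artifact-free
  selection" rule.

## The six-pattern group experiment

The group-level memory stores six stable points — three groups × two
directions — over six jointly selected features. There is no canonical
reference set of six patterns for this design, so the package derives them
from its own synthetic study (they are synthetic stand-ins, recomputed from
scratch at each seed by `group_network()`): features are ranked by a one-way F statistic across the six
group × direction cells (selection "for grouping", not for pooled
direction contrast), and because a six-point memory is only meaningful
with six *distinct* stable states, lower-ranked candidates are swapped in
if two cells would otherwise binarize to the same pattern. Within each
group the LEFT/RIGHT prototypes are complementary by construction (balanced
classes, shared centring), so the network effectively stores three
patterns and their negations.

Probing with 15% distortion (one bit flip of six) over 20 trials, recall
capped at 40 sweeps, yields bit-level performance in the low-to-mid 80s
of percent at most study seeds (the value is quantized — there are only 36
distinct one-bit probes of six patterns — and varies a few points with the
derived pattern set). Increasing the distortion fraction degrades
performance monotonically on average, which the property suite asserts
over 100 seeds with a one-sided sampling allowance.

## Benchmark problem sizes

The test suite uses scaled study variants chosen to exercise every code
path at desk scale: 150-s sessions (2 laps × 6 turns per direction) for
pipeline tests, full 300-s sessions for the structural identities and the
benchmark ordering, 100 planted-recovery simulations, 10,000 random
(net, state) pairs for energy descent, exhaustive state enumeration up to
n = 12, and the full 10-subject study for the group experiment. The
benchmark ordering (per-subject ≥ pooled-selected ≥ best single band ≥
time-domain baseline) is asserted at a fixed seed with a one-sided 0.05
allowance, one binomial standard error at the ~100-probe test sizes — the
true gaps between adjacent stages are genuine but comparable to sampling
noise at desk scale.

## Known limitations

* The synthetic generator plants narrow-band stationary bursts; real
  turn-related EEG is non-stationary, broadband-modulated and spatially
  correlated.
* Storing six patterns in six neurons is far beyond Hebbian capacity by
  design; conclusions about the memory transfer only qualitatively to
  larger networks.
* The EDF writer/reader implements the minimal subset needed for
  round-trip storage (16-bit, one-second records, no annotations).
* Real-data accuracies from the driving paradigm are not reproducible
  without the original recordings and are treated only as a qualitative
  ordering.
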