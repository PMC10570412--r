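---
title: "Staging epileptic EEG from complexity features: models and methods"
author: "epistage package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging epileptic EEG from complexity features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In the pilocarpine rat model of temporal lobe epilepsy, hippocampal EEG
passes through three clinically meaningful states: a *normal* baseline, an
*acute* phase around status epilepticus, and a *chronic* phase marked by
spontaneous recurrent seizures. The acute phase is easy to recognise — the
trace becomes high-amplitude and strongly rhythmic — but chronic-phase EEG
returns close to baseline and is notoriously hard to separate from normal
with linear descriptors such as band power. Nonlinear complexity measures
are more sensitive: chronic EEG is slightly *less* irregular than normal,
and that small, consistent deficit is detectable when several complexity
measures over several channels are combined.

`epistage` implements that programme end to end: band-limited complexity
feature extraction, a graph representation of the eight-channel montage, a
small Chebyshev graph convolutional network (GCNN) classifier, a
statistical comparison layer, and a synthetic EEG generator that stands in
for animal recordings, which are not publicly available.

## Preprocessing

Recordings (8 channels, 1000 Hz, 10 min; 600,000 samples per channel) are
cut into non-overlapping 1-second epochs — 600 epochs of 1,000 samples —
and each epoch is band-limited to the fast-ripple band, 250–500 Hz, by
wavelet subband reconstruction: an orthonormal Haar DWT is taken to the
minimum depth covering the band's lower edge, every level outside the band
(including the approximation) is zeroed, and the signal is rebuilt. At
1000 Hz the 250–500 Hz band is exactly detail level 1, so the filter's
behaviour is unambiguous at the native rate; for other rates the package
keeps every dyadic level `[fs/2^(j+1), fs/2^j]` that overlaps the band.
Filtering is applied per epoch, after segmentation, which keeps epochs
statistically independent of one another. Odd-length inputs are
edge-padded and trimmed after reconstruction; epochs here are always
even-length.

No artifact rejection, notch filtering or re-referencing is performed.

## The five complexity measures

Each epoch is summarised per channel by five measures (column order is
fixed throughout: ApEn, SampEn, PE, FuzzEn, KC):

* **Approximate entropy** (Pincus): `Phi_m(r) − Phi_{m+1}(r)`, where
  `Phi_m` is the mean natural log of the fraction of length-*m* templates
  within Chebyshev distance *r*, self-matches included.
* **Sample entropy** (Richman–Moorman): `−ln(A/B)` over ordered template
  pairs excluding self-matches; *B* counts matches at length *m*, *A* at
  *m* + 1. `A = 0` yields `+Inf`, and `B = 0` is undefined; inside feature
  extraction both are replaced by a documented finite cap (default 10) so
  classifier inputs stay finite. Band-limited 1,000-point epochs can
  genuinely produce these cases.
* **Permutation entropy** (Bandt–Pompe): Shannon entropy of the ordinal
  pattern distribution of order-3, delay-1 embeddings, normalised by
  `ln 3!`. Ties are ranked by order of occurrence — deterministic, and
  measure-zero for continuous signals.
* **Fuzzy entropy** (Chen): like sample entropy but with baseline-removed
  templates and a smooth membership `exp(−(d/r)^n)` instead of the hard
  threshold.
* **Kolmogorov complexity**, operationalised as the Lempel–Ziv-76
  exhaustive-history phrase count of the signal binarised at its median
  (median, not mean, for robustness to the heavy-tailed acute-phase
  amplitudes), normalised by `n / log2(n)`.

Parameters (`complexityParams()`): embedding dimension `m = 2`, tolerance
`r = 0.2 ×` the per-channel sample SD, fuzzy exponent `n = 2`, PE order 3
and delay 1, natural logarithms. These are the dominant conventions of the
EEG-entropy literature; none is prescribed by a data constraint, and all
are exposed in the configuration. With `r` tied to the SD, the three
template entropies are invariant to affine rescaling of the signal, and PE
and KC to any strictly increasing transform — properties the test suite
asserts.

The O(N²) template measures are implemented in C++ and verified, to
1e-12 or exactly, against deliberately naive R oracles (dense distance
matrices, string-search LZ parsing) on dozens of random sequences.

## Graph representation and classifier

Each epoch's 8 × 5 feature matrix becomes a sample on a fixed complete
graph: eight nodes (channels), all 28 undirected edges equal to 1, no
self-loops (self-connection enters through the identity Chebyshev term).
A uniform topology is deliberate — inter-channel similarity patterns may
themselves be stage-dependent, so the graph carries no data-driven
structure that could leak between stages.

The classifier is a two-block ChebNet. Each block applies a Chebyshev
graph convolution `y = Σ_k T_k(L̃) x W_k` (order `K = 3`, weights shared
across the feature axis), max-pools the node axis over fixed adjacent
pairs and the feature axis onto a target length, and applies ReLU:

| stage | tensor |
|---|---|
| input | [B, 1, 8, 5] |
| block 1 (conv 1→10, pool, ReLU) | [B, 10, 4, 3] |
| block 2 (conv 10→20, pool, ReLU) | [B, 20, 2, 1] |
| flatten | [B, 40] |
| FC + ReLU + dropout | [B, 15] |
| FC + softmax | [B, 3] |

`L̃ = 2 L_norm / λ_max − I` is the rescaled normalised Laplacian; for the
complete graph K8 its spectrum is the two-point set {−1, 1/7-scaled}, so
results are insensitive to the exact Chebyshev order. Pooling targets
(nodes 8→4→2, features 5→3→1) follow the printed output sizes; since no
single kernel/stride rule yields both 5→3 and 3→1, pooling is implemented
as target-size max-pooling with left-aligned windows, the last window
absorbing the remainder. Node pairing is fixed — coarsening a uniform
complete graph is degenerate, every pairing is equivalent — which keeps
training deterministic.

Forward, backward and the optimiser are written in plain R array
arithmetic (~1,500 parameters; no GPU or autodiff dependency) and the
backward pass is verified against finite differences. Training is
mini-batch SGD: learning rate 0.001, momentum 0.5, batch size 6,
cross-entropy loss, dropout 0.5 between the FC layers, progress logged
every 10 batches. The published protocol trains 3 epochs for an
individual subject and 50 across subjects; the package default for a
single run is 50, and `runPerSubject()` uses both. The validation set is
scored after every epoch and the best-validation weights are returned.
Initialisation is seeded uniform with ReLU-gain fan-in scaling
(`±sqrt(2/fanin)`); everything is deterministic given the seed.

A convergence note: at this learning rate the network needs on the order
of ten passes before the softmax commits to all three classes, so
short-epoch sanity checks should budget ~15 epochs even on trivially
separable data.

Features are standardised before training — per-feature mean and SD
computed on the *training* set only and applied to all three sets — since
the measures live on very different scales (normalised PE in [0, 1],
capped SampEn up to 10). The split is stratified by class, 50–20–30
train/validation/test, with largest-remainder rounding so sizes always
partition the input.

## Statistical comparison layer

For the group-level contrast the package reproduces the classical layer:
one-way ANOVA of each complexity measure across the three stages
(between/within mean squares, `(k−1, N−k)` degrees of freedom), Tukey HSD
pairwise comparisons via the studentized range distribution, and
2-component PCA scores from the correlation matrix (deterministic sign
convention: the largest-magnitude loading of each component is positive).
ANOVA and Tukey are computed from textbook sums of squares with
`pf()`/`ptukey()` as distribution backends so that toy cases are exactly
checkable by hand; `aov()`/`TukeyHSD()` serve as independent cross-checks
in the tests. "General" baseline features (mean, variance, max, min,
skewness) use the population (1/n) moment convention, consistent with the
moment definition of skewness.

The published group-size arithmetic is honoured: one 10-minute recording
per stage divided into 20 equal epochs across 8 channels gives 160 values
per stage group.

## The synthetic generator

Real recordings from the animal model are not deposited, so the package
ships a generator whose purpose is *not* biophysical realism but moving
band-limited complexity the way epileptogenesis does. Per channel:

    signal = white noise + 1/f-shaped noise + Poisson-timed sinusoidal bursts

White and 1/f noise together carry `noise_sd²` (50 µV, 30% of variance in
the 1/f component); bursts are Hann-windowed sinusoids inside 250–500 Hz
whose rate, amplitude and temporal coverage (`regularity`, implemented as
burst length = regularity / rate) depend on the stage:

| stage | rate (/s) | carrier (Hz) | amplitude (µV) | coverage |
|---|---|---|---|---|
| normal | 0.1 | 320 | 30 | 0.01 |
| acute | 4 | 380 | 400 | 0.95 |
| chronic | 15 | 300 | 55 | 0.5 |

Acute emulates near-continuous high-amplitude rhythm (amplitude 8× the
noise floor); chronic emulates frequent but weak rhythmic events — many
short bursts rather than few long ones, so that every chronic epoch
carries some rhythm and the stage is a *consistent, small* deviation from
normal rather than an intermittent large one; normal is essentially
broadband noise. Under these defaults the band-limited sample entropy
orders normal > chronic > acute with the normal–chronic gap about 6
standard errors (and ~3% of the normal–acute gap) at 600 epochs, and the
default single-subject run (1,800 epochs, 50–20–30 split, published
hyperparameters) reaches test accuracy ≈ 0.98 with per-class F1 ≥ 0.97 —
the package's stand-in for the published per-subject results, not a
reproduction of them.

Channels are statistically independent: the classifier's graph carries
uniform edges, so no cross-channel dependence is needed downstream. What
the generator does *not* emulate: spike/sharp-wave morphology, the
sub-stages of epileptogenesis between the three headline phases, drug
dynamics, inter-channel coherence, or realistic amplitude calibration.
Passing tests on this surrogate therefore demonstrate that the pipeline
recovers *the designed kind* of stage structure from band-limited
complexity; they say nothing about sensitivity to artifacts, montage
differences or biological variability in real data.

Per-subject heterogeneity (for the individual-versus-pooled comparison)
is induced by jittering stage parameters per subject: noise SD ×
U(0.8, 1.25), burst amplitude × U(0.7, 1.3), carrier ± 30 Hz, coverage ×
U(0.8, 1.2).

## Numerical choices and degenerate inputs

* Tolerances `r` are passed to the entropies in absolute units; callers
  (and `extractFeatures()`) scale by the SD. A constant channel returns 0
  for the three template entropies, 0 for PE, and the LZ76 parse of the
  constant string (2 phrases) for KC.
* Sample entropy's undefined/infinite results map to the configurable cap
  (default 10) inside feature extraction, with the raw function keeping
  the mathematical behaviour (+Inf sentinel / error).
* Zero-variance features pass through standardisation with SD treated as
  1 (warning); zero-denominator precision/recall yield 0 with a warning;
  an isolated graph node has its degree treated as 1 with a warning, and
  the empty graph's rescaled Laplacian is −I.
* EDF output quantises onto the 16-bit range mapped to ±5000 µV (typical
  intracranial LFP envelope; widened automatically if exceeded), so
  round-trip error is bounded by half a quantisation step, ~0.076 µV.
* All randomness flows from one seed through a deterministic fan-out, so
  every run directory is reproducible from its resolved configuration.

## Problem sizes used by the checks

The acceptance-style checks run the full published geometry — three 600-s
recordings, 1,800 one-second epochs, 14,400 channel-epoch feature
extractions, 50 training epochs — once, in about ten minutes on one CPU,
and derive the ordering, classification and ANOVA properties from that
single run. Unit tests use 10–150-s recordings and 1–15 training epochs;
oracle comparisons use sequences of length ≤ 200, where the O(N²) naive
implementations are fast.

## Known limitations

* The generator's amplitudes are uncalibrated and channel-independent;
  reference channels behave like signal channels (consistent with the
  observation that references carry similar complexity dynamics).
* The published per-subject protocol of 3 training epochs is honoured in
  `runPerSubject()`, but at the published learning rate it leaves the
  network near the start of its learning curve on synthetic data; the
  pooled 50-epoch setting is the package default for single runs.
* Chronic-versus-normal separation rests on a small mean complexity
  deficit; with fewer than ~100 epochs per stage the stage means are too
  noisy for reliable classification, and the statistical layer is the
  more appropriate tool.
* The statistical layer's printed F/p values on real recordings are not
  reproducible here (the recordings are unavailable); only the qualitative
  pattern — near-zero p for every measure, positive normal-minus-acute
  differences — is asserted.
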