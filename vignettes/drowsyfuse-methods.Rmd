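---
title: "Methods: models, parameters and design choices in drowsyfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in drowsyfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drowsyfuse)
```

# The recognition problem

drowsyfuse models driver-state recognition as four parallel per-second
label streams — EEG fatigue (0/1), ECG fatigue (2/3), phone use (4/5) and
lane keeping (6/7) — fused by a sliding-window majority vote and gated by a
persistence threshold. The two physiological streams are produced by
classifiers over hand-crafted features; the behavioural streams are treated
as inputs (no lane-detection or phone-detection algorithm is part of this
package; the image model classifies static snapshots only).

# Preprocessing

EEG is band-passed 0.15–40 Hz and notched at 50 Hz; ECG is band-passed
0.1–30 Hz and linearly detrended. Choices the contracts leave open:

* **Butterworth order 4, zero phase.** Filters are applied
  forward–backward, so the effective magnitude response is the squared
  one-pass response and no group delay is introduced (a symmetric test
  pulse keeps its peak position to ±1 sample).
* **Second-order sections, not transfer functions.** With a 0.1–0.15 Hz
  edge, poles sit within 1e-3 of z = 1 and the expanded-polynomial filter
  is numerically unusable; the cascade of biquads is well conditioned. The
  band-pass itself is a high-pass/low-pass cascade of order-4 sections for
  the same reason.
* **Even (mirror) padding, pad length ≈ 6 time constants.** The
  conventional odd padding reflects the signal through its first sample
  value, which injects a DC step at the pad/data junction; a near-DC
  high-pass answers that step with a multi-second transient that leaks
  into the data. Mirror padding keeps the local mean continuous, and the
  pad length is derived from the slowest pole radius so edge transients
  decay inside the padding. Residual edge ring-down of the 50 Hz notch (Q
  = 30, time constant ≈ 0.2 s) is why the notch's tone-attenuation test
  measures steady-state (interior) RMS.
* **Filter, then epoch.** The continuous record is filtered before 5 s
  epochs are cut, so no epoch contains a filter edge.

The documented prose describing a "0.15 Hz low-pass and 40 Hz high-pass"
is internally contradictory (it would leave no EEG signal at all); the
implemented behaviour is the band-pass(0.15, 40) its accompanying
pseudocode states.

# EEG features

Eight features per channel: four band powers (δ, θ, α, β per the canonical
band table) and four entropies. Band power is the trapezoidal area under a
Welch PSD (1 s Hann segments, 50 % overlap). Spectral entropy instead uses
a single full-epoch Hann periodogram: entropy of a spectrum needs frequency
resolution — with 1 s segments a pure tone's Hann main lobe alone already
carries ≈ 0.24 normalised entropy — while averaging only reduces variance.
It is normalised by log(#bins) over the 0.15–40 Hz passband to [0, 1].

The printed entropy formulas in the source material are not computable as
stated (the sample-entropy form swaps the m and m+1 roles, the
approximate-entropy form uses an undefined C(m, R+1), and the fuzzy form
gives a Shannon expression with an undefined probability). The package
implements the standard literature definitions instead: Richman–Moorman
sample entropy (self-matches excluded, both template lengths over the same
n − m start points), Pincus approximate entropy (self-matches included) and
Chen-style fuzzy entropy (mean-subtracted templates, membership
exp(−(d/r·SD)^2)). Defaults m = 2, r = 0.2·SD, fuzzy exponent 2. Because r
scales with the series SD, all three are invariant to amplitude scaling.
Degenerate inputs (constant series, zero match counts) yield `NA` with a
warning rather than ±Inf, and such epochs are dropped from feature tables
with a message.

Each implementation is checked against an independent O(n²) double-loop
oracle to 1e-12 on 50 random sequences — the oracles live in the test
helpers and share no code with the package.

# ECG features

R-peaks are found by matched filtering: the kernel is sin evaluated at 15
equally spaced phases from 1.5π to 3.5π (one full cycle, −1 … +1 … −1; ~55
ms at 256 Hz, the width of a QRS complex). The similarity trace is the
sliding cosine between the signal window and the unit-norm kernel — this
normalisation makes detection exactly invariant to amplitude scaling and
time shifts, which the test suite asserts. A floor on the local window norm
(0.5·√15·global RMS) prevents near-silent stretches from producing
spurious high cosines; because the floor is scale-relative, invariance is
preserved. Local maxima above T = 0.3 are kept, a 250 ms refractory period
(≈ 240 bpm ceiling) prunes doubles strongest-first, and each survivor snaps
to the nearest signal maximum within ±50 ms. The 15-tap kernel is literal
(not resampled with fs); `qrs_config(resample_kernel = TRUE)` stretches it
to ~60 ms for unusual sampling rates.

HRV statistics keep the stated denominators verbatim even where they are
nonstandard — RMSSD and SDRR divide by N − 1 while skewness and excess
kurtosis divide by N·SDRR^k with SDRR itself the N − 1 estimator. A
`textbook = TRUE` flag switches skew/kurt to the conventional
sample-moment estimators but is off by default. "N" is the interval count
(one fewer than the peak count), consistent with the mean-RR formula.

# Classifiers

No gradient-boosting, SVM or deep-learning library is assumed at run time,
so the back-ends are self-contained: the default gbdt is an xgboost-style
booster (second-order leaf values, best-first growth, 100 trees, 31
leaves, learning rate 0.1, λ = 1, no subsampling — hence bit-deterministic),
the svm back-end is a full-batch squared-hinge linear SVM on standardised
features, and logistic uses `stats::glm`. The split protocol is a
stratified 80/20 hold-out; stratification is a deliberate strengthening of
a bare 80/20 split to avoid degenerate test sets at desk scale. Splits are
per-epoch; adjacent epochs of one synthetic recording are not independent,
so accuracies here speak to feature separability, not subject-level
generalisation.

# The image model

The architecture is fixed: conv 32→64→128 (all 3×3, valid, ReLU) with 2×2
stride-2 max-pooling after the first two conv layers, flatten, dense 128
and 64 (ReLU), softmax output. The output width defaults to 192 as
documented for the original design even though any plausible class count is
far smaller — it is configurable, and training tests use a 2-unit head.
Pool size/stride and the 64×64×3 input are package choices (the source
states neither). Training is Adam (1e-3) on sparse categorical
cross-entropy with deterministic seeded shuffling and early stop once
training accuracy reaches 99.9 %. Everything (im2col convolution, backprop,
Adam) is base R; at fixture scale (40 images, 64×64) an epoch takes a few
seconds.

# The feedback model

The label matrix appends one column per second; from the fifth column on,
every second a 5 s window yields per-row modes. With binary row alphabets a
5-wide window cannot tie; for custom (even) window sizes ties break toward
the abnormal label (1, 3, 5, 7) — in a safety-critical setting false
alarms are preferred to misses. The mode pattern is looked up in a total
dictionary: by default exactly (1,3,4,7) → severe; (1,3,5,7), (1,3,5,6),
(1,3,4,6) → mild; all other 12 tuples → normal.

The persistence rule needed reconstruction: Δt is defined here as the
number of seconds since the current non-normal dictionary key first
appeared in an unbroken run of windows (0 at first appearance, reset to 0
whenever the key changes), and a severe/mild level is emitted only while
Δt > T. T defaults to 3 s; no authoritative value exists, so it is
config-overridable, and T = ∞ provably silences the system. A second
dictionary (`prose_rule_dictionary()`) encodes the alternative verbal
rules — phone use excuses a lane departure; a departure without phone plus
one abnormal biosignal is severe; a biosignal alone is mild — which
contradict the listed tuples (e.g. (1,3,5,7) is mild in the listed
dictionary but excused in the prose). The listed dictionary is the
default; the prose variant is selectable by config.

# The synthetic world

The generators state the world the tests run in; their defaults are fixed
and were not tuned against test outcomes.

* **EEG** is a sum of band-limited noises (white noise through the order-4
  band filters, each normalised to unit SD) weighted by √(band weight), so
  expected band power is proportional to the weight, plus broadband white
  noise. Filtered noise rather than sinusoids keeps the entropy features
  non-degenerate. The presets encode the conventional drowsiness
  signature — fatigued raises θ (0.7 → 2.4) and α (1.0 → 2.0), lowers β
  (2.2 → 0.7) and carries less broadband noise (SD 0.6 → 0.25, hence more
  regular, lower-entropy traces). These presets are conventions for
  separability testing, not empirical claims about fatigue physiology.
* **ECG** is a train of five Gaussian bumps per beat (P, Q, R, S, T with
  fixed offsets/widths/amplitudes, R dominant at 1.0) at beat times whose
  increments are mean RR + N(0, jitter²) + optional slow sinusoidal drift
  (30 s period). Good enough for matched-filter and HRV testing; it is not
  a biophysical model, contains no noise floor, no ectopy and no
  morphology variation.
* **Label streams** are scripted constant segments; **images** are one
  geometric motif per class with seeded position jitter on a noisy dark
  background.

Consequently a green suite establishes: numerical correctness of features
against oracles, recovery of generator ground truth (R-peak times, RR
statistics, band-power ordering), and end-to-end separability of
deliberately separable classes. It does not establish recognition accuracy
on real recordings — the published external-dataset accuracies are out of
scope here and are intentionally not reproduced.

# File formats and configuration

CSV (comma, mandatory header of channel names, one row per sample, time
implicit) for signals, written at 17 significant digits so round-trips are
exact; feature tables as CSV with a trailing `label` column; label streams
as 4-row CSV; dictionaries and run configuration as JSON; images as ASCII
PPM (P3). JSON replaces YAML and PPM replaces PNG relative to common
practice so the package needs no parsers beyond `jsonlite` and everything
on disk stays plain text.

# Known limitations

* Entropy implementations are O(n²) in epoch length; fine at 5 s × 128 Hz,
  slow for minutes-long epochs.
* The matched filter assumes upright R-waves; inverted leads would need a
  sign flip.
* The gbdt back-end is binary-only (the fusion boundary maps each
  modality's classifier output onto its row alphabet, so multiclass is not
  needed here).
* Per-epoch splitting overstates accuracy whenever epochs within a
  recording are correlated; a grouping column for per-subject splits is
  the intended extension point.
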