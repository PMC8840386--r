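---
title: "Methods: wearable-based SaR-dog behaviour recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable-based SaR-dog behaviour recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sardar)
```

Search-and-rescue dogs signal a find by standing still and barking at the
victim. `sardar` turns the two sensor streams of a back-mounted wearable —
a 100 Hz dual IMU (3-axial accelerometer and gyroscope) and a microphone —
into that binary event. This vignette documents the model, the tunable
parameters, the numerical choices, and what the synthetic-data experiments
do and do not demonstrate.

## IMU channel

Each sensor's axes are collapsed to the orientation-independent magnitude
`S(i) = sqrt(sx² + sy² + sz²)`. The wearable's mounting orientation varies
between dogs and harness fits, and the magnitude is invariant under any
rotation of the device, which is the property the preprocessing relies on
(and which the test suite asserts against random rotation matrices).

Magnitudes are z-normalised, `Z(i) = (S(i) − μ)/σ`, with `μ` and `σ`
estimated **only from training sessions**. This matters: estimating them on
all data leaks the test sessions' scale into training. `sardar_norm_stats`
objects therefore record the ids of the sessions they were fitted on, and
the cross-validation helpers assert that provenance per fold. The standard
deviation uses the population convention (divide by N); the choice is
configurable (`sd_type`) and irrelevant at the sample sizes involved, but it
is pinned for reproducibility.

Label handling: segments must exceed the 2-s window to be usable — a segment
of exactly 2.0 s is kept, since it yields one full window and discarding it
would contradict the window length itself. Unidentifiable ("missing")
stretches are dropped. Windows are 200 samples per sensor, advanced at a 1-s
stride (50% overlap), anchored at the segment start; a trailing remainder
shorter than the stride is discarded rather than padded, so a segment of
`d` seconds yields `floor(d − 2) + 1` windows. Windowing restarts at each
segment boundary — labels are per-segment, and a window straddling two
segments would have no well-defined label. The four field activities merge
into two classes: `standing → stand`, everything else → `search`; the rare
motion classes cannot support leave-one-session-out evaluation on their own.

## Activity network

The 2 × 200 window (accelerometer row first) feeds a late-sensor-fusion CNN:

* conv (1, 11) × 16 + ReLU + max-pool (1, 4) + dropout 0.5
* conv (1, 11) × 24 + ReLU + max-pool (1, 2) + dropout 0.5
* conv (2, 11) × 32 + ReLU + global max-pool + dropout 0.5
* dense 32 → 1 + sigmoid (probability of *stand*)

The (1, ·) kernels of the first two blocks never mix the two sensor rows;
fusion happens only at the (2, 11) block — "late sensor fusion". The test
suite asserts this row-locality directly (row-1 feature maps are invariant
to row-2 content). Total: 21,401 trainable parameters by the closed form
`(kh·kw·c_in + 1)·c_out` per convolution plus `(32 + 1)` for the head.

Convolutions use valid padding and stride 1; pooling uses stride equal to
the pool size with trailing remainders dropped. Parameter counts are
padding-independent, so the totals alone cannot disambiguate the padding
convention; valid padding is the pinned choice.

## Audio channel

Clips are 2 s with 50% overlap, matching the IMU windows so the two decision
streams align one-to-one. Each clip is normalised by its maximum *absolute*
value (dividing by a signed maximum could flip polarity), then transformed to
a log-scaled mel-spectrogram: centered (reflection-padded) STFT with a
periodic Hann window of 1024 samples, hop 512, power spectrum, 128
area-normalised triangular mel filters (HTK mel scale, 0 Hz to Nyquist), and
`log(power + 1e-10)`. At 44.1 kHz a 2-s clip gives `1 + floor(88200/512) =
173` frames; the 173 × 128 input shape in fact *requires* the 44.1 kHz rate
and centered framing (22.05 kHz would give 87 frames, uncentered framing
171), which is how both constants are pinned. Near-silent clips (RMS below
0.01 on the raw amplitude) can be discarded before training; they inflate
the not-bark class without informing the model.

The bark network mirrors the activity network with (3, 3) kernels on the
173 × 128 input: 16/24/32 filters, (2, 2) pooling, global max-pool, dense
32 → 1 sigmoid — 10,617 parameters.

## Training protocol

Adam with learning rate 0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e-8, no decay;
binary cross-entropy (implied by the single sigmoid output); batch size 32
by default. Training runs at least `min_epochs` (500 for activity, 1000 for
bark at full scale) and stops when the monitored quantity — training
accuracy, as the protocol prescribes; validation error is available as an
alternative monitor — has not improved for `patience` (100) epochs. The
returned weights are those of the epoch with the **lowest validation error
rate**.

Two numerical choices deserve note:

* *Checkpoint ties.* With small validation sets the error rate is a coarse,
  plateau-prone monitor: it can sit at its minimum (even exactly zero) for
  many epochs while the decision margins are still growing. Among epochs
  tied on validation error the checkpoint therefore prefers the lowest
  validation loss, and only then the earliest epoch. With realistically
  sized validation sets the rule reduces to plain argmin.
* *Scaled-down schedules.* For the desk-scale experiments below the schedule
  is reduced to `min_epochs = 50`, `patience = 20`, `batch_size = 8`. The
  batch size matters at this scale: a 24-clip training fold at batch 32 is a
  single gradient step per epoch, an order of magnitude fewer optimisation
  steps per epoch than the full-scale protocol; batch 8 keeps the
  steps-per-epoch ratio comparable.

Weight initialisation is uniform with fan-in scaling, seeded; dropout and
shuffling draw from the same seeded stream, so training is exactly
reproducible, and repeated runs with distinct seeds average over
initialisation variance. Dropout is inactive at inference, so predictions
are deterministic.

The CNN arithmetic itself (im2col + BLAS convolutions with compiled
gather/scatter kernels, exact backprop, Adam) is implemented in the package;
the gradient path is verified against central finite differences in the test
suite, and forward convolution/pooling against brute-force oracles.

## Evaluation

Leave-one-session-out: with `n` sessions, fold `j` tests session `j`,
validates session `j+1` (circular), and trains on the rest. Sessions are the
exchangeable unit — windows within a session are heavily correlated (50%
overlap, one dog, one environment), and any split below session granularity
would leak. Metrics are accuracy and F1; F1 is reported as the **macro**
average of the two per-class F1 scores (the positive-class-only F1 is also
returned). Repeated runs are averaged within fold first, then across folds
with equal weight.

The feature baselines (logistic regression, k-NN with k = 5, CART, random
forest with 100 trees — hyperparameters are not part of the reference
protocol and are recorded in the configuration) consume the same normalised
magnitude windows, summarised by seven time-domain statistics per sensor:
mean, min, max, median, population standard deviation, moment skewness and
excess kurtosis (Gaussian → 0; constant input → 0 for both shape
statistics).

## Alert fusion

Both decision streams are 2-s windows on a 1-s stride. Windows are paired
greedily by nearest start time, accepting a pair only when the starts differ
by less than half the stride; unpaired windows are flagged and can never
alert. An alert fires iff a paired window has stand probability and bark
probability both strictly above their thresholds (0.5 by default,
configurable per stream; a probability exactly at threshold classifies
negative — the conservative direction for an alerting system). No debouncing
is applied by default — every qualifying window emits an event — but an
optional `min_consecutive` filter is available. Requiring stand ∧ bark
suppresses the dominant false-alarm mode, barking while moving.

## Synthetic data: what it emulates, and what it does not

No field recordings are distributed with this package, so every statistical
claim is exercised on synthetic data built to reproduce the *structure* the
pipeline depends on:

* 100 Hz dual-sensor sessions of 45–75 s with labelled segments (release
  run, trot/walk search blocks, optional missing stretch, closing stand);
* magnitude variance strictly increasing with activity intensity
  (stand < walk < trot < run) for both sensors — implemented as sinusoidal
  gait oscillation at an activity-specific stride frequency and amplitude
  under a common footfall envelope, Gaussian sensor noise, and gravity on
  one accelerometer axis. The envelope is load-bearing: with independent
  per-axis phases alone, the three oscillations can approximate a constant-
  magnitude rotation whose variance does not grow with amplitude;
* 2-s audio clips at a 6:1 not-bark:bark imbalance — barks as burst trains
  of harmonic pulses (fundamental 400–900 Hz, decaying overtones,
  sharp-attack envelope), not-bark as heavily low-passed rumble with
  footfall transients, separable in the fundamental band by construction;
* session tags throughout, so leave-one-session-out splits exist.

The generator makes no attempt at canine biomechanics or bioacoustics:
amplitudes, stride frequencies and the bark pulse model are caricatures
chosen for separability. Consequently the recovery experiments demonstrate
that the *pipeline* is correct — preprocessing preserves the class signal,
the networks can fit it, cross-validation and fusion account for it honestly
— and they say nothing about accuracy on real dogs, where class overlap,
sensor artefacts and inter-individual variation dominate. The
field numbers (about 94% activity accuracy, about 99% bark accuracy on real
recordings) are not reproducible from this package for that reason; what is
reproducible, and what the acceptance script recomputes, are the exact
architecture parameter budgets (10,617 and ≈21,400) and the metric
arithmetic of the validation confusion tables.

## Problem sizes used in the checks

The recovery experiments run 4 sessions (leave-one-session-out, so each fold
trains on 2 sessions, validates on 1, tests on 1) with 16 clips per session,
and the reduced training schedule above; one run per fold. These sizes are
the package's choice of a desk-scale stand-in: large enough that every
training fold contains both classes and several bark exemplars, small enough
to iterate on quickly. The full-scale protocol (500/1000 minimum epochs,
patience 100, five runs per fold) is the default configuration of
`training_config()` and `default_config()`.

## Known limitations

* The bark-vs-ambient task here is far easier than real bioacoustics; the
  generator's not-bark class contains no vocalisation-like confusers
  (whines, handler speech, wind).
* The alert path assumes the two streams share a clock; the alignment rule
  tolerates sub-stride jitter but not drift.
* Baseline hyperparameters are reasonable defaults, not tuned values; the
  comparison exercises the protocol, not the ranking.
* `glm` logistic regression warns on perfectly separable folds
  (fitted probabilities of 0/1); the fit is still a valid maximum-margin-side
  classifier for prediction, and the warning is suppressed.
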