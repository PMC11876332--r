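---
title: "Inferring phantom temperature from vibroacoustic needle-insertion signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring phantom temperature from vibroacoustic needle-insertion signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Thermotherapies (hyperthermia at roughly 42-48 °C, ablation at 65-75 °C)
need local temperature monitoring, but dedicated interstitial sensors add
invasiveness and MRI thermometry is rarely available where these procedures
happen. When a needle moves through tissue, tool-tissue friction and
puncture events generate structure-borne sound that travels up the shaft to
a microphone clipped to the proximal hub — outside the body. Because the
speed of sound, water's heat capacity and soft-tissue mechanics all vary
with temperature, those vibroacoustic events carry a temperature signature.
`vibrotemp` implements the full analysis chain on which that idea rests,
with a synthetic data generator standing in for laboratory recordings so
that every stage can be exercised and validated offline.

The pipeline: **event detection** (envelope smoothing, local maxima, a
mean-plus-sigma amplitude threshold, peaks-per-centimetre density),
**segmentation** (100 ms waveform chunks, either sliding with 25% overlap
or centred on detected peaks with uniform jitter), **features** (mel
spectrograms: FFT 2048, hop 512, 256 mel bins, 1 Hz-20 kHz),
**regression** (a convolutional network with a single-output head trained
under recording-grouped fivefold cross-validation, AdamW, cosine-annealed
learning rate, MSE loss), and **evaluation** (chunk- and recording-level
RMSE, per-temperature-group delta tables, violin and trace data).

## The synthetic recordings

`simulate_insertion()` reproduces the phase structure of a manual needle
insertion into a water-saturated bubbled foam:

* a `pre_roll` of background noise, then a louder broadband **initiation
  pulse** (20 ms, 4x the event amplitude);
* a quiet **approach** to the foam surface;
* **forward motion** from foam entry `L1` to stop `L2`, during which the
  needle crosses `round(bubble_density * thickness)` bubbles;
* a stationary **dwell** `L2`-`L3`;
* **retraction** `L3`-`L4`, crossing the same bubbles in reverse.

Defaults mirror the laboratory conditions the detector is validated
against: 48 kHz mono audio, insertion speeds drawn uniformly from
5-10 mm/s, 3 cm of foam (1 cm in the fast training demos), reference foams
at 20 and 9 bubbles/cm, and eight 5 °C temperature groups from 20 to 55 °C
with about 22 recordings per group (176 total under the defaults). Within a
group the measured temperature sits up to 1.4 °C below the nominal value —
the waterbath cools between takes — and that ceiling scales down to 20% for
the coldest group, since hot baths cool faster.

Design choices where the generative form was open:

* **Event morphology.** Each bubble crossing is an exponentially damped
  sinusoid (8 ms, decay constant 2 ms) with ±10% amplitude jitter — the
  simplest controllable-spectrum transient.
* **Event placement.** Uniform spacing along the travel path with ±20%
  jitter rather than a Poisson process, so the realized event count equals
  the density target exactly; real foam bubbles are quasi-regular. Event
  count per centimetre is therefore speed-invariant by construction, which
  is the property the peaks-per-cm validation relies on.
* **Temperature encoding.** The generator injects a parametric spectral
  effect: event centre frequency `4000 + 50 * (T - 20)` Hz by default
  (a slope of 50 Hz/°C), optionally with a temperature-dependent decay. The
  real physical encoding is unknown; this monotone stand-in lets us test
  whether the pipeline recovers *an* injected effect, not whether the
  effect is physically accurate.
* **Noise and amplitude.** White Gaussian background (sigma 0.005); event
  peak amplitude 0.05, i.e. 10x the noise sigma (at least 6x is needed for
  the mean-plus-sigma threshold to separate cleanly).

What the generator deliberately does **not** emulate: room noise and its
reference channel, needle-shaft resonances, bubble-size dispersion,
annotation error, or any physically derived temperature dependence.
Passing tests therefore demonstrate internal consistency of the pipeline
and its ability to extract a monotone spectral effect at realistic SNR —
not performance on laboratory recordings.

## Event detection

The detector follows the classical envelope recipe: rectify, smooth with a
20-tap uniform averaging filter applied 4 times (zero-padded,
length-preserving convolution, so peak times stay aligned with the
annotations), locate interior local maxima, and retain those with
amplitude at least `theta = mu + sigma`, where `mu` and `sigma` are the
mean and standard deviation of all candidate amplitudes of that recording.
The rationale: smoothed-noise maxima cluster tightly around their mean
while true needle-bubble events sit far above it, so one standard
deviation above the mean separates the populations.

Conventions the definition leaves open, fixed here and tested under both
options where cheap: `sigma` is the population standard deviation (the
sample convention is available via an argument); candidate statistics are
computed per recording, over the full recording including the initiation
pulse; on a flat plateau the first sample counts as the maximum; no
minimum peak separation is imposed (smoothing merges sub-peaks).

`peak_rate()` converts retained peaks inside `[L1, L2]` into events per
centimetre using the known insertion speed. On synthetic foams at 20 and
9 bubbles/cm the detector recovers both densities within a few percent,
averaged over 20 seeds (`scripts/acceptance.R` recomputes this).

## Segmentation and features

Peak-centred chunks are the primary dataset: one 100 ms chunk per retained
peak, with the peak placed at the chunk centre plus an integer displacement
drawn uniformly from ±25% of the chunk width (a mild augmentation that
stops the network keying on a centred transient). Chunks that would cross
a recording boundary are discarded — shifting them inward would distort the
uniform displacement distribution. The sliding-window dataset (100 ms, 25%
overlap) is retained for comparison but is not the default.

Mel spectrograms use centred Hann frames (FFT 2048, hop 512; a 4800-sample
chunk gives 10 frames), a Slaney-style area-normalized 256-filter bank
from 1 Hz to 20 kHz, and conversion to dB relative to the chunk's maximum
mel energy with a floor at -80 dB. Referencing each chunk to its own
maximum makes features gain-invariant, complementing the gain
augmentation; an all-zero chunk maps to a uniform -80 dB spectrogram.

## Regression model and training

Two architectures share a 1-output head. The default full-scale backbone
is the standard 18-layer residual network (11,177,025 parameters with the
single-output head); spectrograms are replicated to 3 channels and
bilinearly resized to 224x224. Pretrained backbone weights are loaded from
`getOption("vibrotemp.resnet18_weights")` when available; otherwise the
network initializes randomly and the run log records that. The `"small"`
architecture — three conv-batchnorm-ReLU blocks that keep the frequency
axis resolved, a flatten, and a two-layer head — operates directly on the
256x10 spectrogram and exists for CPU-scale experiments and tests.

Training uses recording-grouped fivefold cross-validation: all chunks of a
recording share a fold, so no information leaks between train and test
via recording identity. Fold assignment shuffles recordings, orders them
largest-first by chunk count and greedily fills the smallest fold, which
keeps fold sizes within ±20%. The full schedule is 70 epochs, batch 32,
AdamW (decoupled weight decay 0.01), MSE loss, cosine annealing
`lr(e) = lr_final + (lr_init - lr_final) (1 + cos(pi e / E)) / 2` from
0.001 to 0.0001. Waveform augmentation (order: time stretch 0.9-1.1 by
granular overlap-add, pitch shift ±3 semitones by resampling, gain ±5 dB)
is applied before spectrogram conversion; the stretch range is a
convention of this package, and the pitch unit is interpreted as semitones
since a pitch shift in dB is not well defined.

Numerical choices that matter:

* **Label standardization.** Labels are z-scored on the training folds and
  predictions back-transformed. Temperatures near 37 with spread ~11 would
  otherwise force the head to traverse tens of units at step sizes bounded
  by the learning rate; all reported losses are in °C.
* **Zero-initialized head.** The final dense layer starts at zero, so the
  model begins at the (standardized) label mean and the head aligns before
  the features move — a standard stabilizer for regression heads.
* **Reduced-budget preset.** Short runs (the 10-epoch validation below)
  use `lr_init = 0.003, lr_final = 0.0003`: with an epoch budget cut
  sevenfold, the cosine schedule spends too few steps at a learning rate
  large enough to escape the initial predict-the-mean plateau, and scaling
  the rate up proportionally is the usual remedy. The 70-epoch default
  keeps 0.001 -> 0.0001.
* **Labels are measured temperatures** (continuous), not nominal group
  values; group tables aggregate against measured means.

## What the synthetic validation shows

The package's end-to-end check trains the small network on ~800
peak-centred chunks from 40 recordings (8 groups x 5, 1 cm foam — sizes
chosen so the run finishes in minutes on one CPU) for 10 epochs under
grouped fivefold cross-validation, without augmentation so per-fold
spectrograms can be precomputed. Held-out chunk-level RMSE must beat half
the no-information baseline (the label standard deviation, ~11 °C); in
practice it lands far below it, and per-group mean predictions increase
monotonically with the group label. This demonstrates the pipeline
extracts the injected monotone effect from realistic noise through the
exact leak-free protocol — it does not predict performance on real
recordings, where the temperature encoding, SNR and annotation quality
differ. Reproducing the reported full-scale figures (best RMSE ≈ 3.4 °C on
~4,400 real chunks) requires the publicly deposited dataset and the full
70-epoch schedule; `evaluate_deposited()` wires that run for anyone with a
local copy (`VIBROTEMP_DATA`).

## Degenerate inputs and edge behavior

Empty waveforms, envelopes shorter than 3 samples, zero travel distance,
fewer recordings than folds, and empty result sets raise errors;
zero-candidate envelopes return an empty peak list with
`mu = sigma = theta = 0`; recordings with no in-window chunks yield an
`NA` aggregate (an undefined-prediction marker, never a number);
multi-channel WAVs require an explicit channel; sample-rate mismatches
follow an explicit resample-or-fail flag.

## Known limitations

* The synthetic temperature effect is an assumption, not physics; absolute
  synthetic RMSE numbers say nothing about real tissue.
* Pure-R training is CPU-bound; the full 70-epoch ResNet run on thousands
  of chunks is meant for long offline runs or a future compiled backend.
* The detector is single-band with a global threshold per recording;
  adaptive or matched-filter detection is out of scope.
* Pitch-shift and time-stretch are resampling/overlap-add approximations,
  adequate for augmentation but not transcription-grade.
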