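# vibrotemp

Estimating tissue-phantom temperature from the vibroacoustic signal of a
needle insertion.

When a needle advances through a bubbled, water-saturated foam phantom,
every crossed air bubble emits a structure-borne acoustic transient that a
MEMS microphone on the proximal needle hub picks up. Temperature changes
the mechanics and acoustics of the water-filled foam, so these transients
carry a temperature signature. `vibrotemp` is for signal-processing and
ML researchers who want to study that idea end to end without laboratory
hardware: it generates annotated synthetic insertion recordings, detects
the acoustic events, builds spectrogram datasets, trains a convolutional
regressor under leak-free cross-validation, and summarizes the
predictions.

## Method at a glance

* **Event detection.** The rectified waveform is smoothed with a 20-tap
  uniform averaging filter applied 4 times; all interior local maxima of
  the envelope are candidates, and peaks with amplitude
  `>= theta = mu + sigma` (mean + one standard deviation of the candidate
  amplitudes) are retained. Retained peaks inside the forward-motion
  interval `[L1, L2]`, divided by needle travel, give **peaks per cm** —
  checked against the known bubble densities (~20/cm and ~9/cm) of two
  reference foams.
* **Dataset.** One 100 ms chunk per retained peak, the peak centred with a
  uniform integer displacement of up to ±25% of the chunk width; mel
  spectrograms with FFT 2048, hop 512, 256 mel bins over 1 Hz-20 kHz, in
  dB re chunk maximum.
* **Model.** A convolutional network with a single regression output
  (an 18-layer residual backbone at full scale; a small 3-block CNN for
  CPU runs), trained with AdamW, MSE loss and a cosine-annealed learning
  rate `lr(e) = lr_f + (lr_0 - lr_f)(1 + cos(pi e/E))/2` under fivefold
  cross-validation grouped by recording, so chunks of one recording never
  span the train/test boundary.
* **Evaluation.** Chunk- and recording-level RMSE (°C), per-temperature-
  group tables of measured vs predicted means with their absolute deltas,
  violin-plot distributions, and per-recording prediction traces.

## Worked example

```r
library(vibrotemp)

# one synthetic insertion: 20 bubbles/cm, 3 cm foam, 7 mm/s, 35 degrees C
set.seed(42)
rec <- simulate_insertion(foam_spec(20, 3), insertion_profile(speed = 7),
                          temperature = 35, effect = temperature_effect(),
                          cfg = synth_config())
rec
#> <annotated_recording rec_T35_084055>
#>   12.09 s @ 48000 Hz | group 35 C, measured 35.00 C
#>   L1=2.020 L2=6.306 L3=7.306 L4=11.591 | 120 true events

pk <- detect_peaks(smooth_envelope(rec$waveform), rec$sample_rate)
pk
#> <peak_list> 132 retained / 8957 candidates | mu=0.004786 sigma=0.005288 theta=0.01007 (population)

peak_rate(pk, c(rec$L1, rec$L2), speed = 7)
#> [1] 20
```

The 60 forward-motion bubbles (20/cm x 3 cm) are recovered exactly:
20 peaks/cm. The remaining retained peaks are the initiation pulse and the
mirrored retraction events, which lie outside `[L1, L2]`.

A complete synthetic experiment — generate 40 recordings across eight
temperature groups (20-55 °C), detect peaks, cut ~800 chunks, train the
small CNN for 10 epochs under grouped fivefold CV — runs in a few minutes:

```sh
Rscript inst/cli/vibrotemp.R run-all --seed 1 --epochs 10 --out demo_run
```

and reports held-out chunk-level RMSE of about 2 °C against a
no-information baseline (the label standard deviation) of about 11 °C:
the injected temperature-dependent spectral effect is recovered through
the full pipeline. `demo_run/metrics.json` holds the RMSE, per-fold best
RMSE and the group-table deltas; `predictions.csv` the held-out per-chunk
predictions.

The CLI also exposes the individual stages (`simulate`, `detect-peaks`,
`make-dataset`, `train`, `evaluate`); every run writes a JSON
reproducibility record with its options, seed and package version.

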