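# drowsyfuse

Multi-sensor driver-fatigue recognition from physiological and behavioural
streams, for researchers and engineers prototyping in-vehicle driver-state
monitors. The package covers the full chain:

- **EEG** (two parietal channels, P3/P4 by convention): zero-phase
  band-pass 0.15–40 Hz + 50 Hz notch, then 8 features per channel — band
  powers over δ (0–4 Hz), θ (4–8), α (8–12), β (12–30) as area under the
  Welch PSD, plus sample, approximate, fuzzy and spectral entropy.
- **ECG**: band-pass 0.1–30 Hz + detrend, R-peak detection by matched
  filtering with a one-cycle sine kernel (15 taps from phase 1.5π to 3.5π,
  similarity threshold T = 0.3), then time-domain HRV statistics

  RMSSD = √(Σᵢ(RRᵢ₊₁−RRᵢ)²/(N−1)),  AVRR = ΣRR/N,
  SDRR = √(Σᵢ(RRᵢ−AVRR)²/(N−1)),
  SKEW = Σᵢ(RRᵢ−AVRR)³/(N·SDRR³),  KURT = Σᵢ(RRᵢ−AVRR)⁴/(N·SDRR⁴) − 3.

- **Classifiers**: gradient-boosted trees (default), linear SVM and
  logistic regression behind one train/predict/evaluate contract with a
  stratified 80/20 split.
- **Image model**: a compact CNN (32/64/128 3×3 conv + ReLU, two 2×2
  max-pools, dense 128/64, 192-unit softmax; Adam, sparse categorical
  cross-entropy) for distracted-driving snapshots.
- **Fusion**: a 4-row label matrix (EEG 0/1, ECG 2/3, phone 4/5, lane 6/7)
  grows one column per second; a 5 s sliding window takes per-row modes,
  looks the 4-tuple up in a pattern dictionary (severe / mild / normal),
  and emits a non-normal level only after the key persists for Δt > T
  seconds.

Synthetic generators (`gen_eeg`, `gen_ecg`, `gen_label_stream`,
`gen_images`) provide statistically controlled inputs for every stage, so
the whole pipeline is testable without any external recordings.

## Worked example

```r
library(drowsyfuse)

# synthetic two-channel EEG in each state, 150 s @ 128 Hz
alert <- gen_eeg(eeg_preset("alert",    duration_s = 150, fs = 128, seed = 1))
fatig <- gen_eeg(eeg_preset("fatigued", duration_s = 150, fs = 128, seed = 2))

fa <- extract_eeg_features(epoch_signal(preprocess_eeg(alert), 5, 0, labels = "alert"))
ff <- extract_eeg_features(epoch_signal(preprocess_eeg(fatig), 5, 0, labels = "fatigued"))
features <- feature_table(rbind(as.data.frame(fa)[feature_names(fa)],
                                as.data.frame(ff)[feature_names(ff)]),
                          labels = c(fa$label, ff$label))

ex <- run_experiment(features, train_config("gbdt", seed = 1))
ex$report
#> <eval_report> accuracy 1.0000 on 12 rows
#>
#>            alert fatigued
#>   alert        6        0
#>   fatigued     0        6
round(sort(feature_importance(ex$model), decreasing = TRUE)[1:4], 3)
#> P3_theta  P3_beta P3_delta P3_alpha
#>    0.967    0.033    0.000    0.000
```

The 60 epochs (30 per state) split 48/12; the held-out half-second windows
are perfectly separated, and almost all of the boosted-tree gain sits on θ
band power — the feature the fatigued preset shifts hardest. On the ECG
side:

```r
ge <- gen_ecg(ecg_synth_spec(60, 256, mean_rr_ms = 800, rr_jitter_sd_ms = 20, seed = 3))
peaks <- detect_r_peaks(preprocess_ecg(ge$record))
peaks
#> <rpeak_series> 75 peak(s) @ 256 Hz
str(hrv_features(rr_intervals(peaks)))
#> List of 5
#>  $ rmssd: num 24.8
#>  $ avrr : num 799
#>  $ sdrr : num 17.5
#>  $ skew : num -0.18
#>  $ kurt : num -0.778
```

All 75 simulated beats are recovered; the recovered mean RR (799 ms)
matches the generator's 800 ms and RMSSD reflects the injected 20 ms
beat-to-beat jitter (for i.i.d. jitter RMSSD ≈ √2·σ ≈ 28 ms, shrunk here
by peak-snapping quantisation at 256 Hz).

A command-line interface wrapping the same functions is installed at
`system.file("cli", "drowsyfuse", package = "drowsyfuse")` with
`simulate`, `extract`, `train` and `fuse` subcommands.

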