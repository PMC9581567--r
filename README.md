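# chimeratrf

Tools for asking whether cortical "speech tracking" reflects the
acoustics of speech or speech-specific processing — the logic of auditory
chimera experiments — implemented as a tested R pipeline.

An auditory chimera is built by filtering two stories into matching
frequency bands and, within each band, using the amplitude envelope of
story 1 to modulate the temporal fine structure (TFS) of story 2:

```
partial_b(t) = env_b^{story1}(t) * tfs_b^{story2}(t),   chimera = sum_b partial_b
```

With one band, listeners partially understand the TFS story; with many
bands, the envelope story. Regressing EEG against the stimulus features of
either story then dissociates acoustic from speech-specific envelope
tracking. The regression machinery is the temporal response function
(TRF): a forward encoding model

```
r(t, n) = sum_tau w(tau, n) s(t - tau) + e(t, n),   tau in [-100, 500] ms
```

and a backward decoder `s_hat(t) = sum_n sum_tau R(t + tau, n) g(tau, n)`,
both estimated with ridge regression inside a nested leave-one-out
cross-validation that averages single-trial models and selects the ridge
parameter on inner validation folds. Inference uses trial-shuffle
permutation nulls (derangements), partial-correlation variance
partitioning between feature families (spectrogram vs phonemes), bootstrap
correlation CIs, and exact binomial chance thresholds for behavioral
scores.

The package is organized as:

* **Filter banks & chimera synthesis** — log-spaced near-rectangular (or
  gammatone) cochlear-style banks, band envelope/TFS decomposition,
  `make_chimera()`, RMS normalization, WAV I/O.
* **Stimulus features** — broadband envelope (`broadband_envelope()`),
  envelope recovered from fine structure (`recovered_envelope()`), log-Mel
  spectrogram, phoneme indicator matrices from TSV/TextGrid alignments,
  modulation-spectrum diagnostics.
* **TRF models** — `lag_matrix()`, `ridge_fit()`, `nested_cv()`,
  `predict_forward()`, `reconstruct_stimulus()`,
  `decoder_forward_pattern()`, zero-phase band-pass filtering.
* **Statistics** — `pearson_score()`, `partial_correlation()`,
  `unique_contribution()` (+ permutation nulls), `permutation_null()`,
  `chance_threshold()`, `bootstrap_correlation()`.
* **Synthetic data** — speech-like stimulus pairs (pink-noise carriers
  with 1/f-weighted 1–16 Hz amplitude modulations), gamma-shaped
  ground-truth kernels, simulated EEG at a requested SNR, random phoneme
  alignments; everything a pure function of `(config, seed)`.
* **I/O & pipeline** — a minimal float32+JSON EEG container, trial
  manifests, `run_pipeline()`, and a thin CLI (`inst/cli/chimera`).

## Worked example

Simulate five 10 s trials whose 8-channel EEG is a known gamma-shaped
kernel convolved with a speech-like envelope at 0 dB SNR, then decode the
envelope:

```r
library(chimeratrf)
cfg <- simulation_config(n_trials = 5, trial_duration = 10,
                         audio_rate = 4000, eeg_rate = 64,
                         n_channels = 8, carrier_band = c(80, 1900),
                         seed = 7)
lagspec <- lag_spec(-100, 400, rate = 64)
kern <- make_trf_kernel(120, 60, 8, lagspec, seed = 7)
pairs <- lapply(1:5, function(i) make_speech_like_pair(cfg, seed = i))
env_a <- lapply(pairs, function(p)
  broadband_envelope(p$a, 16, 80, 1900, out_rate = 64))
eeg <- simulate_eeg(env_a, kern, lagspec, snr_db = 0, seed = 99)
trials <- Map(function(f, e) list(features = f, eeg = e), env_a, eeg)
cv <- nested_cv(trials, "backward", lagspec, lambda_grid = 10^(0:6))
cv
#> <trf_cv:backward> 5 trial(s); optimal lambda = 100; mean test r = 0.6476
round(cv$per_trial_scores, 3)
#> [1] 0.615 0.703 0.601 0.645 0.674
```

Each per-trial number is the Pearson correlation between the held-out
trial's true envelope and its reconstruction from EEG alone; ~0.65 at
0 dB SNR says the decoder recovers most of the recoverable envelope
variance. The behavioral chance threshold for 840 four-alternative
questions:

```r
chance_threshold(840, 0.25, 0.05)
#> [1] 27.5
```

— a group score above 27.5% is unlikely (p <= 0.05) under guessing.

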