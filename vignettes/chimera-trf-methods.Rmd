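---
title: "Methods: chimera synthesis, TRF modeling, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chimera synthesis, TRF modeling, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeratrf)
```

## The scientific problem

Cortical activity tracks the slow amplitude fluctuations (the *envelope*)
of speech. That tracking could reflect low-level acoustic processing, or
speech-specific processing, or both. Auditory chimeras let these be pulled
apart: filtering two stories into matching frequency bands and using the
envelope of story 1 to modulate the temporal fine structure (TFS) of
story 2 yields a stimulus whose acoustic energy fluctuations come from one
story while its (partially) intelligible content comes from the other —
and which story is understood flips as the number of bands grows. This
package implements the full computational chain needed to run that logic
on simulated (or real) data: chimera synthesis, stimulus feature
extraction, forward/backward temporal response function (TRF) modeling
with nested cross-validated ridge regression, and permutation/partial-
correlation inference.

## Filter banks and chimera synthesis

Bands are spaced geometrically between `f_low` and `f_high` (80–8020 Hz by
default) — the standard stand-in for a cochlear frequency map when only
the endpoints are specified. Each band's amplitude response is
near-rectangular with raised-cosine transitions centred on the band edges.
Two realization choices matter and were genuinely open:

* **Zero-phase, single-pass application.** Filters are applied as pure
  amplitude responses in the frequency domain (equivalently, linear-phase
  FIRs with exact delay compensation), not forward–backward. A
  forward–backward pass squares the response, and squared responses of
  overlapping neighbours cannot sum to unity; with the single-pass
  realization, adjacent bands cross-fade so that their responses sum to
  exactly one across each seam. Summing all band signals therefore
  reconstructs the band-limited input, which is what makes a self-chimera
  (`make_chimera(x, x, B)`) reconstruct `x` equally well for any band
  count.
* **Band-count-independent outer roll-offs.** The overlap rule ("25% of
  the narrower band's width") fixes interior transitions; the outer
  roll-offs at `f_low` and `f_high` are tied to those frequencies alone,
  so banks with 1, 4 and 16 bands have identical summed responses.

Within each band, the analytic signal (computed by FFT) gives the envelope
(magnitude) and the TFS (cosine of phase); `envelope * tfs` reproduces the
band signal identically. A chimera is the band-wise product of one
stimulus's envelopes with the other's TFS, summed over bands. A gammatone
magnitude response is available as an alternative `shape`. RMS
normalization is a separate, explicit step applied to final stimuli.

## Stimulus representations

* **Env** — mean of `n_bands` (default 128) narrowband Hilbert envelopes
  over 80–8000 Hz, optionally compressed as `20*log10(env + 1e-6)`;
  resampled to the neural rate (128 Hz by default).
* **RE-Env** — envelope *recovered* from fine structure: the broadband TFS
  (cosine of the phase of the whole waveform's analytic signal) is
  filtered into narrow bands whose analytic magnitudes are **summed** (not
  averaged). The mean/sum asymmetry between Env and RE-Env is deliberate
  and retained, as is the 8000 vs 8020 Hz upper edge difference.
* **Sgram** — log-Mel spectrogram: short-time power spectra pooled through
  64 triangular Mel filters spanning 124.1–7284.1 Hz, log-compressed with
  a 1e-10 power floor.
* **Ph** — binary phoneme indicators over a fixed 35-symbol inventory.
  Intervals are half-open `[onset, offset)` so indicators stay mutually
  exclusive at boundaries; unknown labels are dropped with a warning.

Feature resampling to the neural rate uses a zero-phase low-pass at 45% of
the target rate followed by interpolation. (The polyphase resampler in the
`signal` package showed ~15% passband overshoot on plain sinusoids and
was not used.)

## TRF modeling

The forward model is `r(t, n) = sum_tau w(tau, n) s(t - tau) + e(t, n)`
over lags `tau` in −100…+500 ms; the backward (decoder) model integrates
EEG *following* the stimulus sample, `s_hat(t) = sum_n sum_tau
R(t + tau, n) g(tau, n)`, realized by mirroring the lag window on the EEG
side. Lagged designs are zero-padded at trial edges (no trimming, so trial
lengths stay equal); edge samples therefore cost a little accuracy on
short trials, which is why the noiseless-recovery checks use 60 s trials.

Ridge regression penalizes all lagged coefficients equally (`lambda * I`);
the intercept is unpenalized (handled by centering) and features are not
standardized. The nested leave-one-out scheme fits one model per trial per
`lambda` (default grid `10^0 … 10^8`); an outer loop holds out each test
trial while an inner loop scores weight-averaged models (averaging
single-trial fits, never refitting on pooled data) on each validation
trial; the `lambda` maximizing mean validation Pearson r is then used to
average all non-test models and score the test trial. Per-trial designs
and their eigendecompositions do not depend on which responses they are
paired with, so trial-shuffle permutations reuse them — this is what makes
hundreds of full-pipeline permutations affordable.

Forward-model scores average Pearson r over a configurable channel set
(default: all channels; no fixed fronto-temporal subset is hard-wired
because no standard montage is assumed). Decoder weights can be
transformed to interpretable channel topographies via the standard
weight-to-pattern transformation `A = Cov(EEG) G / var(s_hat)`.

Band-limited analyses use zero-phase Chebyshev type-2 band-passes (40 dB
stop-band, stop-band edges half an octave outside the pass-band, order
6 falling back to lower orders and finally to a zero-phase FIR if the IIR
design is unstable). The delta band defaults to 1–4 Hz with the lower edge
configurable.

## Inference

Partial correlations are computed as correlations of regression residuals
(intercept included), which for one covariate equals the recursive
formula. The unique contribution of a feature family is the per-channel
partial correlation between recorded EEG and that family's cross-validated
prediction, controlling for the competing family's prediction.

Permutation nulls re-pair neural responses with the features of a
*different* trial — a derangement, because a uniform shuffle would
occasionally let a trial keep its own features — and rerun the identical
nested-CV pipeline. P-values use the add-one convention
`(1 + #{null >= obs}) / (n_perm + 1)` and are therefore never zero. The
default permutation count is 1000 (configurable; calibration checks in the
test suite use 200). Per-channel p-values can be combined across channels
with Benjamini–Hochberg FDR; cluster-based spatial statistics are out of
scope. The behavioral chance threshold is the `1 - alpha` quantile of the
guessing binomial: `100 * qbinom(1 - alpha, n, p) / n` percent.

## The synthetic-data generator

Real speech is unavailable here; only its modulation statistics matter for
the pipeline's mathematics. A "speech-like" waveform is a band-limited
pink-noise carrier multiplied by a positive envelope whose modulation
spectrum is 1/f-weighted inside 1–16 Hz — slow, delta-dominated energy
fluctuations like narrated speech, with independent draws for the two
members of a stimulus pair. Ground-truth cortical kernels are causal
gamma-shaped responses (default peak 120 ms, width 60 ms, matching the
prominent 100–170 ms response peak) times a smooth random channel
topography; EEG is kernel-convolved features plus 1/f noise scaled per
channel to a requested SNR (0 dB by default). Phoneme sequences tile the
trial back-to-back with log-normal durations (median 80 ms) and Zipf-
distributed labels.

What the generator does **not** emulate: phoneme-to-acoustics coupling,
formant structure, prosody, attention, or any nonlinearity in the
cortical response. Passing tests therefore show that the *pipeline*
recovers what it assumes — linear envelope tracking — not that real EEG
behaves this way.

Default configuration mirrors the target experiment (15 trials x 60 s,
48 kHz audio, 128 Hz EEG, 32 channels). The test suite and acceptance
script run reduced desk-scale versions chosen once for tractability: the
envelope-dominance study uses 20 seeds x (6 trials x 20 s x 8 channels,
4 kHz audio, 64 Hz EEG, 16 envelope bands over 80–1900 Hz); kernel
recovery uses 10 trials x 30 s x 8 channels; p-value calibration uses 200
simulations x 200 permutations at 6 trials x 8 s x 4 channels. Thresholds
(e.g. 18/20 seeds, empirical CDF of p at 0.05 no higher than 0.075,
kernel correlation at least 0.9 within +/-16 ms latency) are independent
of that scaling.

## Numerical choices and degenerate inputs

* FFT lengths are rounded up to 2/3/5-smooth sizes; signals are
  reflect-padded by the longest impulse response before filtering.
* Envelope dB floor `1e-6` (relative to unit-RMS stimuli); spectrogram
  power floor `1e-10`.
* TFS of an exactly zero sample is defined as 1 (envelope 0 annihilates
  the product); an all-zero signal's recovered envelope is returned as
  zeros with a warning.
* All-zero signals cannot be RMS-normalized (error); zero-variance inputs
  to correlation are errors, not NaNs.
* `lambda = 0` on a rank-deficient design returns the minimum-norm
  solution with a warning.
* Every generator is a pure function of `(config, seed)`; independent
  random streams are derived from the master seed by a fixed integer map
  kept below 2^31.

## Worked example

```{r example, eval = FALSE}
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
```

## Known limitations

* The decoder cannot fully invert wide (slow) response kernels: high
  modulation frequencies are attenuated below recoverability, bounding
  noiseless reconstruction accuracy below 1 even with generous lag
  windows.
* Zero-padded trial edges bias scores slightly downward on short trials.
* The near-rectangular bank's perfect-summation property holds for the
  default shape only; the gammatone option does not sum to unity.
* Real-EEG preprocessing (bad-channel interpolation, ICA artifact
  removal) is out of scope; recordings are expected to arrive clean.
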