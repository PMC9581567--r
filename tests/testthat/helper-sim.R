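# Shared fixture builders: everything is generated in code at test time.

# small pink-noise audio signal
mk_noise <- function(n, rate, seed = 1L) {
  set.seed(seed)
  audio_signal(pink_noise(n, rate), rate)
}

# band-limited noise inside the canonical chimera band (scaled to a rate)
mk_band_noise <- function(dur = 2, rate = 24000, seed = 1L,
                          f_low = 80, f_high = 8020) {
  x <- mk_noise(round(dur * rate), rate, seed)
  b <- decompose(x, filterbank_spec(1L, f_low, f_high))$band_signals[1L, ]
  audio_signal(b, rate)
}

# trials of speech-like envelopes driving simulated EEG through a known
# kernel; returns list(trials, feats, eegs, kern, lagspec)
mk_sim_trials <- function(M = 5, dur = 20, rate = 64, nch = 4,
                          snr_db = 200, peak_ms = 120, width_ms = 20,
                          mod_band = c(1, 8), seed = 1L,
                          lagspec = lag_spec(-100, 400, rate = rate)) {
  kern <- make_trf_kernel(peak_ms, width_ms, nch, lagspec,
                          seed = seed + 1000L)
  feats <- lapply(seq_len(M), function(i)
    feature_series(chimeratrf:::with_seed_(seed * 100L + i,
                              chimeratrf:::speech_like_envelope(round(rate * dur),
                                                   rate, mod_band)),
                   rate, "env"))
  eegs <- simulate_eeg(feats, kern, lagspec, snr_db = snr_db,
                       seed = seed + 2000L)
  list(trials = Map(function(f, e) list(features = f, eeg = e),
                    feats, eegs),
       feats = feats, eegs = eegs, kern = kern, lagspec = lagspec)
}

# EEG trials that are pure 1/f noise, independent of any stimulus
mk_noise_eeg <- function(M, dur, rate = 64, nch = 4, seed = 1L) {
  lapply(seq_len(M), function(i)
    eeg_recording(chimeratrf:::with_seed_(as.numeric(seed) * 300 + i,
      t(vapply(seq_len(nch), function(k) pink_noise(round(rate * dur),
                                                    rate),
               numeric(round(rate * dur))))), rate))
}
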