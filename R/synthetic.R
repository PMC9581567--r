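# Synthetic stimuli, ground-truth response kernels and simulated EEG with
# the statistical structure the analysis assumes: speech-like amplitude
# modulations (1/f-weighted, 1-16 Hz), gamma-shaped cortical kernels, and
# 1/f background noise.

#' Simulation configuration
#'
#' Defaults mirror the experimental conditions the pipeline targets:
#' 15 one-minute trials per condition, 48 kHz audio, 128 Hz neural rate,
#' amplitude modulations in 1-16 Hz with a 1/f-weighted modulation
#' spectrum. Smaller values are useful for quick studies; all generators
#' are pure functions of (config, seed).
#'
#' @param n_trials Number of trials (default 15).
#' @param trial_duration Trial length in seconds (default 60).
#' @param audio_rate Audio sampling rate in Hz (default 48000).
#' @param eeg_rate Neural sampling rate in Hz (default 128).
#' @param n_channels EEG channel count (default 32).
#' @param snr_db Per-channel signal-to-noise ratio of simulated EEG in dB
#'   (default 0).
#' @param kernel_peak_ms,kernel_width_ms Ground-truth kernel peak latency
#'   and temporal width in ms (defaults 120 and 60, matching the prominent
#'   100-170 ms response peak).
#' @param mod_band Amplitude-modulation band in Hz (default `c(1, 16)`).
#' @param carrier_band Carrier band in Hz (default `c(80, 8020)`).
#' @param noise_exponent Spectral exponent of the 1/f EEG noise
#'   (default 1).
#' @param seed Integer master seed.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_trials = 15L, trial_duration = 60,
                              audio_rate = 48000, eeg_rate = 128,
                              n_channels = 32L, snr_db = 0,
                              kernel_peak_ms = 120, kernel_width_ms = 60,
                              mod_band = c(1, 16),
                              carrier_band = c(80, 8020),
                              noise_exponent = 1, seed = 1L) {
  if (trial_duration <= 0 || audio_rate <= 0 || eeg_rate <= 0)
    stop("durations and rates must be positive")
  if (!is.finite(snr_db)) stop("`snr_db` must be finite")
  structure(list(n_trials = as.integer(n_trials),
                 trial_duration = trial_duration, audio_rate = audio_rate,
                 eeg_rate = eeg_rate, n_channels = as.integer(n_channels),
                 snr_db = snr_db, kernel_peak_ms = kernel_peak_ms,
                 kernel_width_ms = kernel_width_ms, mod_band = mod_band,
                 carrier_band = carrier_band,
                 noise_exponent = noise_exponent, seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(code)
}

# derive a stream-specific 31-bit sub-seed from the master seed
# (double arithmetic stays exact well beyond 2^31 * 1e5)
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 262144 * 7919 +
                as.numeric(stream) %% 262144 * 104729) %% 2147483629)
}

# positive, unit-mean amplitude envelope with a 1/f-weighted modulation
# spectrum confined to mod_band; generated at `rate`
speech_like_envelope <- function(n, rate, mod_band) {
  nfft <- next_fast_len(n)
  W <- stats::fft(stats::rnorm(nfft))
  f <- (seq_len(nfft) - 1L) / nfft * rate
  f <- pmin(f, rate - f)
  shape <- numeric(nfft)
  inb <- f >= mod_band[1L] & f <= mod_band[2L]
  shape[inb] <- 1 / sqrt(pmax(f[inb], mod_band[1L]))
  z <- Re(stats::fft(W * shape, inverse = TRUE))[seq_len(n)] / nfft
  z <- z / stats::sd(z)
  env <- pmax(1 + 0.5 * z, 0)
  env / mean(env)
}

#' Generate a pair of independent speech-like waveforms
#'
#' Each waveform is a band-limited pink-noise carrier amplitude-modulated
#' by an independent positive envelope whose modulation spectrum is
#' 1/f-weighted within `mod_band` -- the modulation statistics (slow,
#' delta-dominated energy fluctuations) that the chimera/TRF pipeline
#' relies on, without any linguistic content.
#'
#' @param config A [simulation_config].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return List with [audio_signal]s `a` and `b` and the ground-truth
#'   envelopes `env_a`, `env_b` (at the audio rate).
#' @export
make_speech_like_pair <- function(config = simulation_config(),
                                  seed = config$seed) {
  n <- round(config$trial_duration * config$audio_rate)
  rate <- config$audio_rate
  cb <- config$carrier_band
  gen <- function(s) {
    with_seed_(s, {
      carrier <- pink_noise(n, rate, exponent = 1)
      env <- speech_like_envelope(n, rate, config$mod_band)
      list(env = env, sig = carrier * env)
    })
  }
  ga <- gen(sub_seed(seed, 11L))
  gb <- gen(sub_seed(seed, 23L))
  band_limit <- function(x) {
    dec <- decompose(audio_signal(x, rate),
                     filterbank_spec(1L, cb[1L], cb[2L]))
    dec$band_signals[1L, ]
  }
  list(a = audio_signal(band_limit(ga$sig), rate),
       b = audio_signal(band_limit(gb$sig), rate),
       env_a = ga$env, env_b = gb$env)
}

#' Ground-truth gamma-shaped TRF kernel
#'
#' A causal gamma-shaped temporal response peaking at `peak_ms` with
#' spread `width_ms`, multiplied by a smooth random channel topography
#' (rank-1 kernel). The temporal argmax is identical across channels.
#'
#' @param peak_ms Peak latency in ms; must lie inside the lag window.
#' @param width_ms Temporal spread (~2 SD) in ms; the width -> 0 limit
#'   approaches a single-lag impulse.
#' @param n_channels Number of channels.
#' @param lagspec A [lag_spec].
#' @param seed Integer seed for the topography.
#' @return Array `n_lags x 1 x n_channels` (one feature), with attributes
#'   `temporal` and `topography`.
#' @export
make_trf_kernel <- function(peak_ms, width_ms, n_channels,
                            lagspec = lag_spec(), seed = 1L) {
  lag_ms <- lagspec$lag_ms
  if (peak_ms <= min(lag_ms) || peak_ms >= max(lag_ms))
    stop("`peak_ms` must lie strictly inside the lag window")
  s <- max(width_ms, 1e-3) / 2
  theta <- (-peak_ms + sqrt(peak_ms^2 + 4 * s^2)) / 2
  shape_k <- peak_ms / theta + 1
  h <- numeric(length(lag_ms))
  pos <- lag_ms > 0
  h[pos] <- stats::dgamma(lag_ms[pos], shape = shape_k, scale = theta)
  if (max(h) == 0) stop("degenerate kernel; increase `width_ms`")
  h <- h / max(h)
  topo <- with_seed_(seed, {
    idx <- seq_len(n_channels)
    raw <- rep(0, n_channels)
    for (k in 1:3)
      raw <- raw + stats::rnorm(1) *
        sin(2 * pi * k * idx / n_channels + stats::runif(1, 0, 2 * pi))
    0.25 + abs(raw) / max(abs(raw), 1e-12)
  })
  kern <- array(0, dim = c(length(lag_ms), 1L, n_channels))
  for (ch in seq_len(n_channels)) kern[, 1L, ch] <- h * topo[ch]
  attr(kern, "temporal") <- h
  attr(kern, "topography") <- topo
  kern
}

#' Simulate EEG from stimulus features and ground-truth kernels
#'
#' Generates each trial's EEG as the sum over feature families of the
#' kernel-convolved features plus 1/f noise, with the noise scaled per
#' channel so that 10*log10(signal power / noise power) equals `snr_db`.
#'
#' @param features List of [feature_series] (one per trial), or a list of
#'   lists when multiple feature families drive the response.
#' @param kernels A kernel array (from [make_trf_kernel()]) or list of
#'   kernel arrays matching the feature families.
#' @param lagspec The [lag_spec] the kernels are defined on.
#' @param snr_db Per-channel SNR in dB.
#' @param noise_exponent 1/f exponent of the additive noise (default 1).
#' @param seed Integer seed for the noise.
#' @return List of [eeg_recording]s, one per trial, each carrying the
#'   noiseless signal in attribute `"clean"`.
#' @export
simulate_eeg <- function(features, kernels, lagspec = lag_spec(),
                         snr_db = 0, noise_exponent = 1, seed = 1L) {
  if (length(features) == 0L) stop("empty feature list")
  single_family <- inherits(features[[1L]], "feature_series")
  kernel_list <- if (is.list(kernels)) kernels else list(kernels)
  out <- vector("list", length(features))
  for (i in seq_along(features)) {
    fam <- if (single_family) list(features[[i]]) else features[[i]]
    if (length(fam) != length(kernel_list))
      stop("number of feature families does not match kernels")
    clean <- NULL
    for (k in seq_along(fam)) {
      mdl <- trf_model(kernel_list[[k]],
                       bias = rep(0, dim(kernel_list[[k]])[3L]),
                       lagspec = lagspec)
      pk <- predict_forward(mdl, fam[[k]])
      clean <- if (is.null(clean)) pk else clean + pk
    }
    nch <- ncol(clean); nt <- nrow(clean)
    noise <- with_seed_(sub_seed(seed, i), {
      vapply(seq_len(nch), function(ch)
        pink_noise(nt, lagspec$rate, exponent = noise_exponent),
        numeric(nt))
    })
    sig_pow <- colMeans(clean^2)
    noi_pow <- colMeans(noise^2)
    scale <- sqrt(sig_pow / (noi_pow * 10^(snr_db / 10)))
    eeg <- t(clean + sweep(noise, 2L, scale, `*`))
    rec <- eeg_recording(eeg, lagspec$rate)
    attr(rec, "clean") <- t(clean)
    out[[i]] <- rec
  }
  out
}

#' Generate a random phoneme alignment sequence
#'
#' Back-to-back, non-overlapping records tiling `[0, duration)`: durations
#' are log-normal with the requested median, labels are drawn from a
#' Zipf-like (1/rank) distribution over the inventory.
#'
#' @param duration Total duration in seconds.
#' @param inventory Label inventory (default [phoneme_inventory()]).
#' @param mean_dur_ms Median phoneme duration in ms (default 80).
#' @param seed Integer seed.
#' @return [alignment_records] tiling the duration exactly.
#' @export
make_phoneme_sequence <- function(duration, inventory = phoneme_inventory(),
                                  mean_dur_ms = 80, seed = 1L) {
  if (duration <= 0) stop("`duration` must be positive")
  with_seed_(seed, {
    n_guess <- ceiling(duration * 1000 / mean_dur_ms * 2) + 10L
    durs <- stats::rlnorm(n_guess, meanlog = log(mean_dur_ms / 1000),
                          sdlog = 0.4)
    ends <- cumsum(durs)
    n_use <- which(ends >= duration)[1L]
    durs <- durs[seq_len(n_use)]
    ends <- ends[seq_len(n_use)]
    ends[n_use] <- duration
    starts <- c(0, ends[-n_use])
    pr <- (1 / seq_along(inventory))
    labels <- sample(inventory, n_use, replace = TRUE, prob = pr / sum(pr))
    alignment_records(labels, starts, ends)
  })
}
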