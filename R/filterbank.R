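#' Cochlear-style band-pass filter bank specification
#'
#' Bands are spaced geometrically ("logarithmically") between `f_low` and
#' `f_high`, the standard engineering stand-in for a cochlear frequency map
#' when only the endpoints are known. Adjacent pass-bands overlap by
#' `overlap_fraction` of the bandwidth of the narrower (lower) band.
#'
#' @param n_bands Number of bands (>= 1).
#' @param f_low,f_high Band-edge extremes in Hz, `0 < f_low < f_high`.
#' @param overlap_fraction Fraction of the narrower band's width over which
#'   adjacent filters overlap (default 0.25).
#' @param shape `"near-rectangular"` (default) or `"gammatone"`.
#' @return A `filterbank_spec` object.
#' @export
filterbank_spec <- function(n_bands, f_low = 80, f_high = 8020,
                            overlap_fraction = 0.25,
                            shape = c("near-rectangular", "gammatone")) {
  shape <- match.arg(shape)
  if (n_bands < 1L) stop("`n_bands` must be >= 1")
  if (!(0 < f_low && f_low < f_high)) stop("need 0 < f_low < f_high")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)")
  structure(list(n_bands = as.integer(n_bands), f_low = f_low,
                 f_high = f_high, overlap_fraction = overlap_fraction,
                 shape = shape),
            class = "filterbank_spec")
}

# Equivalent rectangular bandwidth of the human auditory filter at fc (Hz).
erb_hz <- function(fc) 24.7 * (4.37 * fc / 1000 + 1)

#' Realize a filter bank at a sampling rate
#'
#' Near-rectangular filters are realized as zero-phase amplitude responses
#' with raised-cosine transitions centred on the geometric band edges; the
#' transition width at each interior edge equals `overlap_fraction` times
#' the narrower neighbouring band's width, so adjacent responses cross at
#' half amplitude and sum to exactly one across each seam. Gammatone
#' filters use the standard 4th-order gammatone magnitude response at the
#' bands' geometric centre frequencies (applied zero phase).
#'
#' @param spec A [filterbank_spec].
#' @param rate Sampling rate (Hz) of the signals to be filtered.
#' @return A `filterbank` object with band `edges`, per-band pass-bands,
#'   transition widths, and impulse responses.
#' @export
build_filterbank <- function(spec, rate) {
  stopifnot(inherits(spec, "filterbank_spec"))
  if (spec$f_high >= rate / 2)
    stop("f_high must be below the Nyquist frequency (rate/2)")
  nb <- spec$n_bands
  edges <- exp(seq(log(spec$f_low), log(spec$f_high), length.out = nb + 1L))
  widths <- diff(edges)
  # frequency-resolution guard: 1 s is the longest impulse response used,
  # so the resolution is ~1 Hz; bands must span at least 2 bins
  if (any(widths < 2))
    stop("too many bands: a band narrower than 2 frequency bins resulted")
  # transition width at interior edge j: overlap_fraction * narrower width;
  # outer roll-offs depend only on the frequency extremes (not on n_bands)
  # so that banks with different band counts sum to the same response
  tw <- numeric(nb + 1L)
  if (nb > 1L)
    tw[2:nb] <- spec$overlap_fraction * pmin(widths[-nb], widths[-1L])
  tw[1L] <- min(0.2 * spec$f_low, widths[1L])
  tw[nb + 1L] <- min(0.05 * spec$f_high, widths[nb],
                     rate / 2 - spec$f_high)
  centers <- sqrt(edges[-1L] * edges[-(nb + 1L)])
  fb <- structure(list(spec = spec, rate = rate, edges = edges,
                       centers = centers, transition_widths = tw),
                  class = "filterbank")
  fb$impulse_responses <- lapply(seq_len(nb), function(b)
    fb_impulse_response(fb, b))
  fb
}

# Amplitude response of band b on a (folded) frequency grid.
fb_response <- function(fb, fr, b) {
  sp <- fb$spec
  if (sp$shape == "gammatone") {
    fc <- fb$centers[b]
    bw <- 1.019 * erb_hz(fc)
    h <- (1 + ((fr - fc) / bw)^2)^(-2)
    h / max(h)
  } else {
    rc_band_mask(fr, fb$edges[b], fb$edges[b + 1L],
                 fb$transition_widths[b], fb$transition_widths[b + 1L])
  }
}

# Centered FIR impulse response of band b (for serialization/inspection);
# length is 4 periods of the band's low edge, capped at 1 s.
fb_impulse_response <- function(fb, b) {
  L <- min(round(4 * fb$rate / fb$edges[b]), round(fb$rate))
  if (L %% 2L == 0L) L <- L + 1L
  nfft <- next_fast_len(4L * L)
  freqs <- (seq_len(nfft) - 1L) / nfft * fb$rate
  fr <- pmin(freqs, fb$rate - freqs)
  h <- Re(stats::fft(fb_response(fb, fr, b) + 0i, inverse = TRUE)) / nfft
  h <- c(h[(nfft - (L - 1L) / 2L + 1L):nfft], h[1:((L + 1L) / 2L)])
  h * hamming_(L)
}

#' @export
print.filterbank <- function(x, ...) {
  cat(sprintf("<filterbank> %d %s band(s), %.1f-%.1f Hz @ %g Hz\n",
              x$spec$n_bands, x$spec$shape, x$spec$f_low, x$spec$f_high,
              x$rate))
  invisible(x)
}

#' Serialize a filter bank description to JSON
#'
#' @param fb A `filterbank`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
filterbank_to_json <- function(fb, path = NULL) {
  desc <- list(n_bands = fb$spec$n_bands, f_low = fb$spec$f_low,
               f_high = fb$spec$f_high,
               overlap_fraction = fb$spec$overlap_fraction,
               shape = fb$spec$shape, rate = fb$rate,
               edges = fb$edges, centers = fb$centers,
               transition_widths = fb$transition_widths,
               impulse_response_lengths =
                 vapply(fb$impulse_responses, length, 1L))
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    write_atomic(js, path)
    return(invisible(js))
  }
  js
}

#' Decompose a signal into band envelopes and fine structure
#'
#' Each band of the bank is applied with zero phase; the band's analytic
#' signal then yields the envelope (magnitude) and the temporal fine
#' structure (cosine of the phase). Envelope times fine structure
#' reconstructs the band signal exactly.
#'
#' @param signal An [audio_signal].
#' @param spec A [filterbank_spec] or a realized `filterbank`.
#' @return A `band_decomposition` with matrices `band_signals`,
#'   `band_envelopes`, `band_tfs` (all `n_bands x n_samples`).
#' @export
decompose <- function(signal, spec) {
  signal <- as_audio_signal(signal)
  if (anyNA(signal$samples)) stop("input contains NA")
  fb <- if (inherits(spec, "filterbank")) spec
        else build_filterbank(spec, signal$rate)
  if (!isTRUE(all.equal(fb$rate, signal$rate)))
    stop("filterbank rate does not match signal rate")
  maxlen <- max(vapply(fb$impulse_responses, length, 1L))
  if (length(signal$samples) <= maxlen)
    stop("signal shorter than the longest filter impulse response")
  nb <- fb$spec$n_bands
  z <- apply_masks(signal$samples, function(fr, b) fb_response(fb, fr, b),
                   nb, signal$rate, npad = maxlen, analytic = TRUE)
  n <- length(signal$samples)
  env <- matrix(0, nb, n)
  tfs <- matrix(0, nb, n)
  bs <- matrix(0, nb, n)
  for (b in seq_len(nb)) {
    env[b, ] <- Mod(z[[b]])
    bs[b, ] <- Re(z[[b]])
    tf <- bs[b, ] / env[b, ]
    tf[!is.finite(tf)] <- 1
    tfs[b, ] <- tf
  }
  structure(list(band_signals = bs, band_envelopes = env, band_tfs = tfs,
                 spec = fb$spec, rate = signal$rate),
            class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat(sprintf("<band_decomposition> %d band(s) x %d samples @ %g Hz\n",
              nrow(x$band_envelopes), ncol(x$band_envelopes), x$rate))
  invisible(x)
}

#' Triangular Mel-scale filter bank
#'
#' `n_filters` triangular filters with centre frequencies equally spaced on
#' the Mel scale between `f_low` and `f_high`, for log-Mel spectrograms.
#'
#' @param n_filters Number of filters.
#' @param f_low,f_high Centre-frequency extremes in Hz.
#' @param rate Sampling rate of the signals to be analysed (Hz).
#' @param n_fft FFT length whose bins the filters are sampled on.
#' @return A `mel_filterbank` with `centers` (Hz) and `weights`
#'   (`n_filters x (n_fft/2 + 1)`).
#' @export
build_mel_filterbank <- function(n_filters, f_low = 124.1, f_high = 7284.1,
                                 rate, n_fft = 1024L) {
  if (!(0 < f_low && f_low < f_high && f_high < rate / 2))
    stop("need 0 < f_low < f_high < rate/2")
  if (n_filters < 1L) stop("`n_filters` must be >= 1")
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  mpts <- seq(mel(f_low), mel(f_high), length.out = n_filters + 2L)
  fpts <- imel(mpts)
  bin_f <- (0:(n_fft / 2)) * rate / n_fft
  W <- matrix(0, n_filters, length(bin_f))
  for (k in seq_len(n_filters)) {
    lo <- fpts[k]; ce <- fpts[k + 1L]; hi <- fpts[k + 2L]
    up <- bin_f >= lo & bin_f <= ce
    dn <- bin_f > ce & bin_f <= hi
    W[k, up] <- (bin_f[up] - lo) / (ce - lo)
    W[k, dn] <- (hi - bin_f[dn]) / (hi - ce)
  }
  structure(list(n_filters = as.integer(n_filters), f_low = f_low,
                 f_high = f_high, rate = rate, n_fft = as.integer(n_fft),
                 centers = fpts[2:(n_filters + 1L)],
                 mel_centers = mpts[2:(n_filters + 1L)], weights = W),
            class = "mel_filterbank")
}

# Pooled narrowband Hilbert envelope (mean or sum across bands) without
# materializing the full band decomposition; the workhorse behind the
# broadband and recovered envelope features.
pooled_band_envelope <- function(signal, fb, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  maxlen <- max(vapply(fb$impulse_responses, length, 1L))
  if (length(signal$samples) <= maxlen)
    stop("signal shorter than the longest filter impulse response")
  nb <- fb$spec$n_bands
  z <- apply_masks(signal$samples, function(fr, b) fb_response(fb, fr, b),
                   nb, signal$rate, npad = maxlen, analytic = TRUE)
  acc <- numeric(length(signal$samples))
  for (b in seq_len(nb)) acc <- acc + Mod(z[[b]])
  if (reduce == "mean") acc / nb else acc
}
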