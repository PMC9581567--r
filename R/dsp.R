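# Shared DSP primitives: analytic signals, zero-phase FIR low-pass,
# spectrum-domain band filtering, resampling, 1/f noise.

next_fast_len <- function(n) {
  # smallest 2^a * 3^b * 5^c >= n keeps the FFTs cheap
  if (n <= 2L) return(2L)
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose real part is `x`, whose
#' magnitude is the instantaneous amplitude envelope and whose phase angle
#' carries the temporal fine structure.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for an analytic representation")
  if (anyNA(x) || !all(is.finite(x))) stop("input contains non-finite values")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Reflect-pad a vector on both sides by npad samples.
reflect_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  c(rev(x[2:(npad + 1L)]), x, rev(x[(n - npad):(n - 1L)]))
}

# Raised-cosine cross-fade amplitude mask evaluated on frequency grid f:
# 1 inside [lo_hi[1]+w_lo/2, lo_hi[2]-w_hi/2]-ish flat region, cosine roll
# across transition regions centred on the edges, 0 outside. Adjacent masks
# built with shared edges and widths sum to exactly 1 across the seam.
rc_band_mask <- function(f, lo, hi, w_lo, w_hi) {
  m <- numeric(length(f))
  flat <- f >= (lo + w_lo / 2) & f <= (hi - w_hi / 2)
  m[flat] <- 1
  if (w_lo > 0) {
    tr <- f > (lo - w_lo / 2) & f < (lo + w_lo / 2)
    m[tr] <- 0.5 * (1 + sin(pi * (f[tr] - lo) / w_lo))
  } else m[f >= lo & f <= (hi - w_hi / 2)] <- 1
  if (w_hi > 0) {
    tr <- f > (hi - w_hi / 2) & f < (hi + w_hi / 2)
    m[tr] <- 0.5 * (1 - sin(pi * (f[tr] - hi) / w_hi))
  }
  m
}

# Apply a set of amplitude masks (rows of `masks` over the rfft grid of the
# padded length) to x with zero phase.  Returns filtered real signals, and
# optionally per-band analytic signals (filter + Hilbert in one pass).
apply_masks <- function(x, mask_fun, n_bands, rate, npad, analytic = FALSE) {
  n <- length(x)
  xp <- reflect_pad(x, npad)
  npad <- (length(xp) - n) %/% 2L
  nfft <- next_fast_len(length(xp))
  xp <- c(xp, numeric(nfft - length(xp)))
  X <- stats::fft(xp)
  freqs <- (seq_len(nfft) - 1L) / nfft * rate
  # fold: frequencies above Nyquist map to their negative-frequency mirror
  fr <- pmin(freqs, rate - freqs)
  out <- vector("list", n_bands)
  sel <- (npad + 1L):(npad + n)
  for (b in seq_len(n_bands)) {
    m <- mask_fun(fr, b)
    if (analytic) {
      half <- freqs <= rate / 2
      Y <- X * m
      Y[!half] <- 0
      Y[half] <- Y[half] * ifelse(freqs[half] %in% c(0, rate / 2), 1, 2)
      z <- stats::fft(Y, inverse = TRUE) / nfft
      out[[b]] <- z[sel]
    } else {
      y <- Re(stats::fft(X * m, inverse = TRUE)) / nfft
      out[[b]] <- y[sel]
    }
  }
  out
}

# Zero-phase low-pass with a raised-cosine transition around the cutoff,
# applied in the frequency domain (reflect-padded), used for resampling
# and the FIR fallback of the EEG band-pass.
fir_lowpass_zerophase <- function(x, cutoff, rate, trans = NULL) {
  if (is.null(trans)) trans <- min(0.3 * cutoff, rate / 2 - cutoff)
  npad <- min(length(x) - 1L, ceiling(4 * rate / max(trans, 1e-6)))
  apply_masks(x, function(fr, b)
    rc_band_mask(fr, 0, cutoff, 0, trans), 1L, rate, npad)[[1L]]
}

sinc_ <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
hamming_ <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

#' Resample a uniformly sampled series
#'
#' Anti-aliased arbitrary-ratio resampling: when downsampling, a zero-phase
#' windowed-sinc low-pass at 45% of the target rate precedes linear
#' interpolation onto the target grid.
#'
#' @param x Numeric vector.
#' @param from,to Original and target sampling rates (Hz).
#' @return Numeric vector of length `round(length(x) * to / from)`.
#' @export
resample_series <- function(x, from, to) {
  if (from <= 0 || to <= 0) stop("rates must be positive")
  n_out <- max(1L, as.integer(round(length(x) * to / from)))
  if (isTRUE(all.equal(from, to))) return(x)
  if (to < from) x <- fir_lowpass_zerophase(x, cutoff = 0.45 * to, rate = from)
  t_in <- (seq_along(x) - 1L) / from
  t_out <- (seq_len(n_out) - 1L) / to
  stats::approx(t_in, x, xout = pmin(t_out, max(t_in)))$y
}

#' 1/f ("pink") noise
#'
#' Gaussian noise whose amplitude spectrum is shaped as f^(-exponent/2),
#' i.e. power falling as 1/f^exponent, standardized to unit variance.
#'
#' @param n Number of samples.
#' @param rate Sampling rate (Hz), used only to anchor the spectral axis.
#' @param exponent Spectral slope of the power spectrum (default 1).
#' @return Numeric vector of length `n` with mean ~0, sd 1.
#' @export
pink_noise <- function(n, rate = 1, exponent = 1) {
  nfft <- next_fast_len(n)
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- (seq_len(nfft) - 1L) / nfft * rate
  f <- pmin(f, rate - f)
  shape <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}
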