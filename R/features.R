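#' Time-aligned stimulus feature series
#'
#' Container for univariate or multivariate stimulus representations
#' sampled at the neural analysis rate (128 Hz by default elsewhere).
#'
#' @param values Numeric matrix `n_features x n_samples` (a vector is taken
#'   as one feature).
#' @param rate Sampling rate in Hz.
#' @param kind One of `"env"`, `"re_env"`, `"sgram"`, `"phonemes"`,
#'   `"other"`.
#' @param feature_labels Optional character vector of row labels.
#' @return A `feature_series` object.
#' @export
feature_series <- function(values, rate,
                           kind = c("env", "re_env", "sgram", "phonemes",
                                    "other"),
                           feature_labels = NULL) {
  kind <- match.arg(kind)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!all(is.finite(values))) stop("feature values must be finite")
  if (kind == "phonemes") {
    if (!all(values %in% c(0, 1))) stop("phoneme features must be binary")
    if (any(colSums(values) > 1))
      stop("phoneme features must be mutually exclusive per sample")
  }
  if (is.null(feature_labels)) feature_labels <-
      paste0(kind, seq_len(nrow(values)))
  if (length(feature_labels) != nrow(values))
    stop("feature_labels length must match the number of rows")
  structure(list(values = values, rate = rate, kind = kind,
                 feature_labels = feature_labels),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series:%s> %d feature(s) x %d samples @ %g Hz\n",
              x$kind, nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}

n_samples <- function(fs) ncol(fs$values)

#' Broadband amplitude envelope
#'
#' The signal is band-pass filtered into `n_bands` log-spaced bands, the
#' Hilbert envelope of each band is taken, and the narrowband envelopes are
#' averaged into a broadband envelope. Optionally compressed to decibels
#' (20 log10), reflecting the compressive relationship between stimulus
#' amplitude and cortical response, then resampled to the neural rate.
#'
#' @param signal An [audio_signal].
#' @param n_bands Number of analysis bands (default 128).
#' @param f_low,f_high Band extremes in Hz (defaults 80 and 8000).
#' @param db Convert to dB via `20*log10(env + eps)`?
#' @param eps Floor added before the log (default 1e-6; relevant only with
#'   `db = TRUE`).
#' @param out_rate Neural sampling rate for the output (default 128 Hz).
#' @return A [feature_series] of kind `"env"`.
#' @export
broadband_envelope <- function(signal, n_bands = 128L, f_low = 80,
                               f_high = 8000, db = FALSE, eps = 1e-6,
                               out_rate = 128) {
  signal <- as_audio_signal(signal)
  fb <- build_filterbank(filterbank_spec(n_bands, f_low, f_high),
                         signal$rate)
  env <- pooled_band_envelope(signal, fb, reduce = "mean")
  if (db) {
    if (eps <= 0 && any(env == 0))
      stop("log of zero envelope; use a positive `eps`")
    env <- 20 * log10(env + eps)
  }
  env <- resample_series(env, signal$rate, out_rate)
  feature_series(pmax(env, if (db) -Inf else 0), out_rate, kind = "env",
                 feature_labels = "envelope")
}

#' Envelope recovered from temporal fine structure
#'
#' Models the cochlear recovery of envelope cues from a chimera's fine
#' structure: the broadband temporal fine structure (cosine of the phase of
#' the whole waveform's analytic signal) is filtered into `n_bands`
#' narrow bands, and the per-band analytic magnitudes are summed (not
#' averaged) into the broadband recovered envelope.
#'
#' @inheritParams broadband_envelope
#' @return A [feature_series] of kind `"re_env"`.
#' @export
recovered_envelope <- function(signal, n_bands = 128L, f_low = 80,
                               f_high = 8020, out_rate = 128) {
  signal <- as_audio_signal(signal)
  if (all(signal$samples == 0)) {
    warning("all-zero input: fine-structure phase undefined; returning zeros")
    n_out <- max(1L, round(length(signal$samples) * out_rate / signal$rate))
    return(feature_series(numeric(n_out), out_rate, kind = "re_env",
                          feature_labels = "re_envelope"))
  }
  z <- analytic_signal(signal$samples)
  tfs <- cos(Arg(z))
  fb <- build_filterbank(filterbank_spec(n_bands, f_low, f_high),
                         signal$rate)
  re_env <- pooled_band_envelope(audio_signal(tfs, signal$rate), fb,
                                 reduce = "sum")
  re_env <- resample_series(re_env, signal$rate, out_rate)
  feature_series(re_env, out_rate, kind = "re_env",
                 feature_labels = "re_envelope")
}

#' Log-Mel spectrogram at the neural rate
#'
#' Short-time power spectra are pooled through a triangular Mel filter bank
#' and compressed with a logarithmic nonlinearity; frames are then aligned
#' to the neural sampling rate.
#'
#' @param signal An [audio_signal].
#' @param n_filters Number of Mel filters (default 64).
#' @param f_low,f_high Mel-bank extremes in Hz (defaults 124.1 and 7284.1).
#' @param eps Power floor before the log (default 1e-10).
#' @param out_rate Neural sampling rate (default 128 Hz).
#' @return A [feature_series] of kind `"sgram"` (`n_filters x T`).
#' @export
log_mel_spectrogram <- function(signal, n_filters = 64L, f_low = 124.1,
                                f_high = 7284.1, eps = 1e-10,
                                out_rate = 128) {
  signal <- as_audio_signal(signal)
  rate <- signal$rate
  hop <- max(1L, round(rate / out_rate))
  win <- 2L * hop
  n_fft <- next_fast_len(max(win, 512L))
  mel <- build_mel_filterbank(n_filters, f_low, f_high, rate, n_fft)
  x <- signal$samples
  n <- length(x)
  starts <- seq(1L, max(1L, n - win + 1L), by = hop)
  w <- hamming_(win)
  P <- matrix(0, n_fft %/% 2L + 1L, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1L)]
    seg[is.na(seg)] <- 0
    X <- stats::fft(c(seg * w, numeric(n_fft - win)))
    P[, i] <- Mod(X[1:(n_fft %/% 2L + 1L)])^2
  }
  S <- log(mel$weights %*% P + eps)
  # frame i is centred at (starts[i]-1 + win/2)/rate; re-grid to out_rate
  t_frames <- (starts - 1 + win / 2) / rate
  n_out <- max(1L, round(n * out_rate / rate))
  t_out <- (seq_len(n_out) - 1L) / out_rate
  V <- matrix(0, n_filters, n_out)
  for (k in seq_len(n_filters))
    V[k, ] <- stats::approx(t_frames, S[k, ], xout = t_out, rule = 2L)$y
  feature_series(V, out_rate, kind = "sgram",
                 feature_labels = sprintf("mel_%.1fHz", mel$centers))
}

#' Canonical 35-symbol phoneme inventory
#'
#' A fixed, ordered ARPAbet-style inventory of the 35 phonemes retained for
#' indicator coding (rare symbols excluded). The order is part of the
#' contract: serialized feature matrices index rows by it.
#'
#' @return Character vector of length 35.
#' @export
phoneme_inventory <- function() {
  c("AA", "AE", "AH", "AO", "AW", "AY", "B", "CH", "D", "DH", "EH", "ER",
    "EY", "F", "G", "HH", "IH", "IY", "JH", "K", "L", "M", "N", "NG",
    "OW", "P", "R", "S", "SH", "T", "TH", "UH", "UW", "V", "W")
}

#' Phoneme alignment records
#'
#' @param label Character vector of phoneme symbols.
#' @param onset,offset Numeric vectors of onset/offset times in seconds.
#' @return A data.frame with class `alignment_records`, sorted by onset.
#' @export
alignment_records <- function(label, onset, offset) {
  if (!(length(label) == length(onset) && length(onset) == length(offset)))
    stop("label/onset/offset lengths differ")
  if (any(onset < 0) || any(offset <= onset))
    stop("need 0 <= onset < offset for every record")
  df <- data.frame(label = as.character(label), onset = as.numeric(onset),
                   offset = as.numeric(offset),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset), , drop = FALSE]
  if (nrow(df) > 1L && any(df$onset[-1L] < df$offset[-nrow(df)] - 1e-9))
    stop("alignment records overlap")
  class(df) <- c("alignment_records", "data.frame")
  df
}

#' Read phoneme alignments from a 3-column TSV
#'
#' Expected columns: label, onset (s), offset (s); a header row is detected
#' and skipped automatically.
#'
#' @param path Path to the TSV file.
#' @return [alignment_records].
#' @export
read_alignment_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1L]][2L])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  alignment_records(df[[1L]], df[[2L]], df[[3L]])
}

#' Read phoneme alignments from a Praat TextGrid
#'
#' Parses an interval tier (default: the first tier whose name contains
#' "phone", case-insensitively) of a long- or short-format TextGrid.
#' Empty-label intervals (silences) are dropped.
#'
#' @param path Path to the TextGrid file.
#' @param tier Regular expression selecting the tier by name.
#' @return [alignment_records].
#' @export
read_alignment_textgrid <- function(path, tier = "phone") {
  lines <- readLines(path, warn = FALSE)
  tier_starts <- grep("name\\s*=|^\\s*\"[^\"]*\"\\s*$", lines)
  name_lines <- grep("name\\s*=", lines)
  if (length(name_lines) == 0L) stop("no interval tiers found in ", path)
  names <- sub('.*name\\s*=\\s*"([^"]*)".*', "\\1", lines[name_lines])
  hit <- grep(tier, names, ignore.case = TRUE)
  if (length(hit) == 0L) stop("no tier matching '", tier, "' in ", path)
  from <- name_lines[hit[1L]]
  to <- if (hit[1L] < length(name_lines)) name_lines[hit[1L] + 1L]
        else length(lines)
  block <- lines[from:to]
  xmin <- as.numeric(sub(".*xmin\\s*=\\s*([0-9.eE+-]+).*", "\\1",
                         grep("xmin\\s*=", block, value = TRUE)))
  xmax <- as.numeric(sub(".*xmax\\s*=\\s*([0-9.eE+-]+).*", "\\1",
                         grep("xmax\\s*=", block, value = TRUE)))
  text <- sub('.*text\\s*=\\s*"([^"]*)".*', "\\1",
              grep("text\\s*=", block, value = TRUE))
  # first xmin/xmax pair describes the tier itself, the rest the intervals
  if (length(xmin) == length(text) + 1L) {
    xmin <- xmin[-1L]; xmax <- xmax[-1L]
  }
  keep <- nzchar(trimws(text))
  alignment_records(trimws(text)[keep], xmin[keep], xmax[keep])
}

#' Binary phoneme indicator matrix
#'
#' One row per inventory symbol; row r is 1 on samples falling inside the
#' half-open interval `[onset, offset)` of a record labelled
#' `inventory[r]`. Half-open intervals keep the indicators mutually
#' exclusive at record boundaries. Records with labels outside the
#' inventory are dropped with a warning (mirroring the exclusion of rare
#' phonemes).
#'
#' @param records [alignment_records].
#' @param inventory Ordered character vector of labels
#'   (default [phoneme_inventory()]).
#' @param rate Sampling rate (Hz) of the output matrix.
#' @param duration Total duration (s) of the output.
#' @return A [feature_series] of kind `"phonemes"` (`|inventory| x T`).
#' @export
phoneme_matrix <- function(records, inventory = phoneme_inventory(),
                           rate = 128, duration) {
  n_t <- round(duration * rate)
  M <- matrix(0, length(inventory), n_t)
  rownames(M) <- inventory
  unknown <- setdiff(unique(records$label), inventory)
  if (length(unknown) > 0L)
    warning("dropping records with labels outside the inventory: ",
            paste(unknown, collapse = ", "))
  recs <- records[records$label %in% inventory, , drop = FALSE]
  for (i in seq_len(nrow(recs))) {
    on <- recs$onset[i]; off <- recs$offset[i]
    if (on >= duration) next
    if (off > duration + 1e-9) {
      warning("record extends beyond `duration`; truncating")
      off <- duration
    }
    # sample t (1-based) covers time (t-1)/rate; active iff in [on, off)
    t0 <- as.integer(ceiling(on * rate - 1e-9)) + 1L
    t1 <- as.integer(ceiling(off * rate - 1e-9))
    if (t1 < t0) next
    M[recs$label[i], t0:min(t1, n_t)] <- 1
  }
  feature_series(M, rate, kind = "phonemes", feature_labels = inventory)
}

#' Delta/theta modulation-spectrum ratio
#'
#' Ratio of the mean amplitude-spectrum magnitude of a (univariate) feature
#' series in `band_a` to that in `band_b`. With the defaults this is the
#' delta (1-4 Hz) to theta (4-8 Hz) modulation energy ratio of an
#' envelope.
#'
#' @param series A [feature_series] with one row, or a numeric vector plus
#'   `rate`.
#' @param band_a,band_b Frequency bands (Hz) as length-2 vectors.
#' @param rate Sampling rate, required when `series` is a bare vector.
#' @return Positive scalar ratio.
#' @export
modulation_ratio <- function(series, band_a = c(1, 4), band_b = c(4, 8),
                             rate = NULL) {
  if (inherits(series, "feature_series")) {
    x <- drop(series$values[1L, ]); rate <- series$rate
  } else {
    if (is.null(rate)) stop("`rate` required for a bare vector")
    x <- as.numeric(series)
  }
  if (rate <= 2 * band_b[2L]) stop("sampling rate too low for `band_b`")
  if (length(x) < rate / band_a[1L])
    stop("series shorter than one cycle of the lowest analysis frequency")
  x <- x - mean(x)
  A <- Mod(stats::fft(x))[1:(length(x) %/% 2L + 1L)]
  f <- (seq_along(A) - 1L) * rate / length(x)
  in_a <- f >= band_a[1L] & f <= band_a[2L]
  in_b <- f >= band_b[1L] & f <= band_b[2L]
  if (!any(in_a) || !any(in_b)) stop("series too short to resolve the bands")
  mean(A[in_a]) / mean(A[in_b])
}

#' Write a feature series to labelled delimited text with a JSON sidecar
#' @param fs A [feature_series].
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_series <- function(fs, path) {
  df <- as.data.frame(t(fs$values))
  names(df) <- fs$feature_labels
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  file.rename(tmp, path)
  write_atomic(jsonlite::toJSON(list(rate = fs$rate, kind = fs$kind,
                                     feature_labels = fs$feature_labels),
                                auto_unbox = TRUE, digits = NA),
               paste0(path, ".json"))
  invisible(path)
}

#' Read a feature series written by [write_feature_series()]
#' @param path TSV path with a `<path>.json` sidecar.
#' @return A [feature_series].
#' @export
read_feature_series <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar file: ", side)
  meta <- jsonlite::fromJSON(side)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  feature_series(t(as.matrix(df)), meta$rate, kind = meta$kind,
                 feature_labels = meta$feature_labels)
}
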