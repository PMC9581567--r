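#' Audio signal container
#'
#' A minimal container for a mono sampled waveform: a numeric vector of
#' dimensionless amplitudes plus its sampling rate in Hz.
#'
#' @param samples Numeric vector of finite amplitudes (length >= 1).
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `rate`.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.2f s), rms %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

duration_s <- function(x) length(x$samples) / x$rate

as_audio_signal <- function(x, rate = NULL) {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(rate)) stop("`rate` required when coercing a numeric vector")
  audio_signal(x, rate)
}

#' Root-mean-square amplitude
#' @param signal An `audio_signal` or numeric vector.
#' @return RMS value.
#' @export
signal_rms <- function(signal) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else signal
  sqrt(mean(x^2))
}

#' Read a mono WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit, and IEEE float32 encodings. Multichannel
#' files are rejected: all stimulus processing here is monaural.
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        rate         = readBin(fmt_raw[5:8], "integer", 1L, 4L,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$n_channels != 1L)
        stop("only mono WAV is supported; file has ", fmt$n_channels,
             " channels")
      n <- sz %/% (fmt$bits %/% 8L)
      x <- if (fmt$audio_format == 3L && fmt$bits == 32L) {
        readBin(con, "double", n, 4L, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n, 2L, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
        raw3 <- readBin(con, "raw", n * 3L)
        b <- matrix(as.integer(raw3), nrow = 3L)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop("unsupported WAV encoding: format ", fmt$audio_format,
             ", ", fmt$bits, " bits")
      }
      return(audio_signal(x, fmt$rate))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
}

#' Write a mono WAV file
#'
#' @param signal An [audio_signal].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly. If peak amplitude exceeds 1 for 16-bit output
#'   the waveform is scaled down on write (with a warning); the in-memory
#'   signal is never clipped.
#' @export
write_wav <- function(signal, path, bits = 16L) {
  signal <- as_audio_signal(signal)
  x <- signal$samples
  if (bits == 16L && max(abs(x)) > 1) {
    warning("peak amplitude > 1; scaling to full-scale on write")
    x <- x / max(abs(x))
  }
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wb")
  bytes_per <- bits %/% 8L
  data_sz <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  fmt_code <- if (bits == 32L) 3L else 1L
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(as.integer(round(signal$rate)), con, 4L, endian = "little")
  writeBin(as.integer(round(signal$rate) * bytes_per), con, 4L,
           endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4L, endian = "little")
  if (bits == 32L) {
    writeBin(x, con, 4L, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)), con,
             2L, endian = "little")
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Resample an audio signal
#'
#' Anti-aliased resampling: a zero-phase windowed-sinc low-pass at 45% of
#' the target rate followed by interpolation onto the new sample grid.
#'
#' @param signal An [audio_signal].
#' @param target_rate New sampling rate in Hz.
#' @return Resampled [audio_signal] of length
#'   `round(length * target_rate / rate)`.
#' @export
resample_audio <- function(signal, target_rate) {
  signal <- as_audio_signal(signal)
  y <- resample_series(signal$samples, signal$rate, target_rate)
  audio_signal(y, target_rate)
}
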