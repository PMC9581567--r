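#' Chimera synthesis specification
#'
#' @param n_bands Number of frequency bands (1, 4 and 16 are the canonical
#'   conditions).
#' @param filterbank A [filterbank_spec]; defaults to the canonical
#'   80-8020 Hz log-spaced bank with `n_bands` bands.
#' @param env_source_id,tfs_source_id Optional labels recording which
#'   stimulus donates the envelope and which the fine structure.
#' @return A `chimera_spec` object.
#' @export
chimera_spec <- function(n_bands,
                         filterbank = filterbank_spec(n_bands),
                         env_source_id = "env_source",
                         tfs_source_id = "tfs_source") {
  if (filterbank$n_bands != n_bands)
    stop("filterbank n_bands must equal the chimera n_bands")
  structure(list(n_bands = as.integer(n_bands), filterbank = filterbank,
                 env_source_id = env_source_id,
                 tfs_source_id = tfs_source_id),
            class = "chimera_spec")
}

#' Synthesize a multiband auditory chimera
#'
#' Both sources are decomposed with the same filter bank; within each band
#' the envelope of `env_source` modulates the temporal fine structure of
#' `tfs_source`, and the resulting partial chimeras are summed into the
#' final stimulus. The operation is deliberately asymmetric: swapping the
#' sources swaps which sound's amplitude dynamics survive.
#'
#' @param env_source,tfs_source [audio_signal]s at the same rate. If their
#'   lengths differ both are trimmed to the shorter with a warning.
#' @param spec A [chimera_spec].
#' @param keep_partials Keep the per-band partial chimeras in the result?
#' @return A `chimera_stimulus` with elements `audio` ([audio_signal]),
#'   `spec`, and optionally `partial_chimeras` (`n_bands x n_samples`).
#' @export
make_chimera <- function(env_source, tfs_source, spec,
                         keep_partials = FALSE) {
  env_source <- as_audio_signal(env_source)
  tfs_source <- as_audio_signal(tfs_source)
  if (!isTRUE(all.equal(env_source$rate, tfs_source$rate)))
    stop("source rates differ")
  n <- min(length(env_source$samples), length(tfs_source$samples))
  if (length(env_source$samples) != length(tfs_source$samples)) {
    warning("sources differ in length; trimming to the shorter")
    env_source$samples <- env_source$samples[seq_len(n)]
    tfs_source$samples <- tfs_source$samples[seq_len(n)]
  }
  fb <- build_filterbank(spec$filterbank, env_source$rate)
  de <- decompose(env_source, fb)
  dt <- decompose(tfs_source, fb)
  partials <- de$band_envelopes * dt$band_tfs
  out <- colSums(partials)
  res <- list(audio = audio_signal(out + 0, env_source$rate), spec = spec)
  if (keep_partials) res$partial_chimeras <- partials
  structure(res, class = "chimera_stimulus")
}

#' @export
print.chimera_stimulus <- function(x, ...) {
  cat(sprintf("<chimera_stimulus> %d band(s): env <- '%s', tfs <- '%s'\n",
              x$spec$n_bands, x$spec$env_source_id, x$spec$tfs_source_id))
  print(x$audio)
  invisible(x)
}

#' Normalize a signal to a target RMS intensity
#'
#' Pure rescaling; the waveform shape is untouched.
#'
#' @param signal An [audio_signal] (or numeric vector with `rate`
#'   attribute-free use via [audio_signal]).
#' @param target_rms Target root-mean-square amplitude (> 0).
#' @return Rescaled [audio_signal].
#' @export
normalize_rms <- function(signal, target_rms = 0.1) {
  signal <- as_audio_signal(signal)
  r <- signal_rms(signal)
  if (r == 0) stop("cannot normalize an all-zero signal")
  if (target_rms <= 0) stop("`target_rms` must be positive")
  audio_signal(signal$samples * (target_rms / r), signal$rate)
}

#' Serialize a chimera specification to a JSON sidecar
#' @param spec A [chimera_spec].
#' @param path Optional output path.
#' @return JSON string.
#' @export
chimera_spec_to_json <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(list(
    n_bands = spec$n_bands,
    f_low = spec$filterbank$f_low, f_high = spec$filterbank$f_high,
    overlap_fraction = spec$filterbank$overlap_fraction,
    shape = spec$filterbank$shape,
    env_source_id = spec$env_source_id,
    tfs_source_id = spec$tfs_source_id), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    write_atomic(js, path)
    return(invisible(js))
  }
  js
}
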