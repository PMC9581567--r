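# Readers/writers for the minimal EEG container, trial manifests, and the
# end-to-end pipeline orchestration.

# write-temp-then-rename so readers never observe a partial file
write_atomic <- function(text, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(as.character(text), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write an EEG recording to the binary container
#'
#' Raw little-endian float32 matrix (row-major, channels x samples) plus a
#' JSON sidecar `<path>.json` holding the rate, channel names and storage
#' order. A TSV fallback (`format = "tsv"`) writes samples as rows with
#' channel-name headers.
#'
#' @param eeg An [eeg_recording].
#' @param path Output path (conventionally `.f32` for binary).
#' @param format `"bin"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(eeg, path, format = c("bin", "tsv")) {
  format <- match.arg(format)
  side <- jsonlite::toJSON(list(rate = eeg$rate,
                                channel_names = eeg$channel_names,
                                n_channels = nrow(eeg$data),
                                n_samples = ncol(eeg$data),
                                order = "row-major",
                                byte_order = "little",
                                format = format),
                           auto_unbox = TRUE, digits = NA)
  tmp <- paste0(path, ".tmp")
  if (format == "bin") {
    con <- file(tmp, "wb")
    writeBin(as.numeric(t(eeg$data))[seq_len(length(eeg$data))], con,
             size = 4L, endian = "little")
    close(con)
  } else {
    df <- as.data.frame(t(eeg$data))
    names(df) <- eeg$channel_names
    utils::write.table(df, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  file.rename(tmp, path)
  write_atomic(side, paste0(path, ".json"))
  invisible(path)
}

#' Read an EEG recording written by [write_eeg()]
#'
#' @param path Path to the container; the sidecar `<path>.json` must
#'   exist.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar file: ", side_path)
  meta <- jsonlite::fromJSON(side_path)
  if (!is.null(meta$byte_order) && meta$byte_order != "little")
    stop("unknown byte order: ", meta$byte_order)
  if (identical(meta$format, "tsv")) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    return(eeg_recording(t(as.matrix(df)), meta$rate,
                         meta$channel_names))
  }
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n + 1L, size = 4L, endian = "little")
  if (length(x) != n)
    stop("matrix size does not match the sidecar (expected ", n,
         " float32 values, found ", length(x), ")")
  eeg_recording(matrix(x, nrow = meta$n_channels, byrow = TRUE),
                meta$rate, meta$channel_names)
}

#' Resample an EEG recording to a lower rate
#'
#' Anti-aliased decimation (zero-phase low-pass at 45% of the target rate
#' followed by interpolation onto the target grid); upsampling is out of
#' scope and rejected.
#'
#' @param eeg An [eeg_recording].
#' @param target_rate Target rate in Hz, `<=` the current rate.
#' @return Resampled [eeg_recording] with
#'   `round(n * target_rate / rate)` samples.
#' @export
resample_eeg <- function(eeg, target_rate) {
  if (target_rate > eeg$rate)
    stop("upsampling EEG is not supported")
  if (isTRUE(all.equal(target_rate, eeg$rate))) return(eeg)
  out <- t(apply(eeg$data, 1L, resample_series, from = eeg$rate,
                 to = target_rate))
  eeg_recording(out, target_rate, eeg$channel_names)
}

#' Trial manifest
#'
#' One row per trial: identifiers, file paths and condition labels tying
#' stimuli, alignments and EEG together.
#'
#' @param trial_id Character or integer trial identifiers.
#' @param stimulus_wav,alignment_file,eeg_file File paths (alignment may
#'   be `NA`).
#' @param n_bands Chimera condition (number of bands).
#' @param env_source,tfs_source Story-role labels.
#' @return A data.frame of class `trial_manifest`.
#' @export
trial_manifest <- function(trial_id, stimulus_wav, alignment_file = NA,
                           eeg_file, n_bands, env_source = "story1",
                           tfs_source = "story2") {
  df <- data.frame(trial_id = as.character(trial_id),
                   stimulus_wav = stimulus_wav,
                   alignment_file = alignment_file, eeg_file = eeg_file,
                   n_bands = n_bands, env_source = env_source,
                   tfs_source = tfs_source, stringsAsFactors = FALSE)
  class(df) <- c("trial_manifest", "data.frame")
  df
}

check_manifest <- function(manifest) {
  for (col in c("stimulus_wav", "eeg_file")) {
    missing <- !file.exists(manifest[[col]])
    if (any(missing))
      stop("manifest references missing file(s): ",
           paste(manifest[[col]][missing], collapse = ", "))
  }
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           force = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the chimera tracking pipeline over a trial manifest
#'
#' For every chimera condition in the manifest: reads the stimulus WAVs
#' and EEG, computes broadband envelopes of both source stories (from the
#' per-trial source WAVs recorded in the manifest attributes or from the
#' chimera itself for the recovered envelope), runs backward nested-CV
#' decoding of each story's envelope, and writes a results table with one
#' row per (condition, story, statistic). Every artifact carries a
#' provenance record (config hash, seed).
#'
#' @param manifest A [trial_manifest] whose `stimulus_wav` column points
#'   at the *chimera* WAVs, with attributes `env_wavs` and `tfs_wavs`
#'   giving the per-trial source-story WAVs (as written by
#'   [simulate_dataset()]).
#' @param out_dir Output directory for results and model sidecars.
#' @param eeg_rate Neural analysis rate (Hz).
#' @param env_bands Number of bands for envelope extraction (128 in the
#'   canonical analysis; reduce for quick runs).
#' @param env_range Envelope band extremes in Hz.
#' @param lagspec A [lag_spec] at `eeg_rate`.
#' @param lambda_grid Ridge grid for [nested_cv()].
#' @param n_permutations Permutations for the trial-shuffle null
#'   (0 disables).
#' @param seed Integer seed recorded in the provenance and used for the
#'   permutation null.
#' @param verbose Log stage boundaries?
#' @return Data frame of results (also written to
#'   `<out_dir>/results.tsv`).
#' @export
run_pipeline <- function(manifest, out_dir, eeg_rate = 128,
                         env_bands = 32L, env_range = c(80, 3800),
                         lagspec = lag_spec(rate = eeg_rate),
                         lambda_grid = 10^(0:6), n_permutations = 0L,
                         seed = 1L, verbose = TRUE) {
  check_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env_wavs <- attr(manifest, "env_wavs")
  tfs_wavs <- attr(manifest, "tfs_wavs")
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  rows <- list()
  for (nb in sort(unique(manifest$n_bands))) {
    sub <- manifest[manifest$n_bands == nb, , drop = FALSE]
    idx <- match(sub$trial_id, manifest$trial_id)
    say("condition ", nb, "-band: ", nrow(sub), " trial(s)")
    eegs <- lapply(sub$eeg_file, read_eeg)
    eegs <- lapply(eegs, function(e)
      if (e$rate > eeg_rate) resample_eeg(e, eeg_rate) else e)
    feats <- list(
      env_story = lapply(env_wavs[idx], function(p)
        broadband_envelope(read_wav(p), n_bands = env_bands,
                           f_low = env_range[1L], f_high = env_range[2L],
                           out_rate = eeg_rate)),
      tfs_story = lapply(tfs_wavs[idx], function(p)
        broadband_envelope(read_wav(p), n_bands = env_bands,
                           f_low = env_range[1L], f_high = env_range[2L],
                           out_rate = eeg_rate)))
    for (story in names(feats)) {
      say("  decoding ", story, " envelope")
      trials <- lapply(seq_along(eegs), function(i) {
        fs <- feats[[story]][[i]]
        nmin <- min(ncol(fs$values), ncol(eegs[[i]]$data))
        list(features = feature_series(fs$values[, seq_len(nmin),
                                                 drop = FALSE],
                                       fs$rate, kind = fs$kind),
             eeg = eeg_recording(eegs[[i]]$data[, seq_len(nmin),
                                                drop = FALSE],
                                 eegs[[i]]$rate,
                                 eegs[[i]]$channel_names))
      })
      cv <- nested_cv(trials, "backward", lagspec, lambda_grid)
      null_mean <- NA_real_; null_q95 <- NA_real_; p <- NA_real_
      if (n_permutations > 0L) {
        say("  permutation null (", n_permutations, ")")
        nd <- permutation_null(trials, function(tr)
          nested_cv(tr, "backward", lagspec, lambda_grid)$mean_score,
          n_permutations = n_permutations, seed = seed,
          observed = cv$mean_score)
        null_mean <- mean(nd$scores)
        null_q95 <- unname(stats::quantile(nd$scores, 0.95))
        p <- nd$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = paste0(nb, "-band"), story = story,
        statistic = "reconstruction_r", observed = cv$mean_score,
        optimal_lambda = cv$optimal_lambda, null_mean = null_mean,
        null_q95 = null_q95, p = p)
      model_info <- list(direction = "backward", n_bands = nb,
                         story = story, lambda = cv$optimal_lambda,
                         lag_ms = c(lagspec$t_min, lagspec$t_max),
                         per_trial_scores = cv$per_trial_scores,
                         seed = seed)
      write_atomic(jsonlite::toJSON(model_info, auto_unbox = TRUE,
                                    digits = NA),
                   file.path(out_dir, sprintf("decoder_%dband_%s.json",
                                              nb, story)))
    }
  }
  res <- do.call(rbind, rows)
  prov <- list(seed = seed, eeg_rate = eeg_rate, env_bands = env_bands,
               lambda_grid = lambda_grid,
               config_hash = config_hash(list(eeg_rate = eeg_rate,
                                              env_bands = env_bands,
                                              lambda_grid = lambda_grid,
                                              seed = seed)),
               package_version =
                 as.character(utils::packageVersion("chimeratrf")))
  write_atomic(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "provenance.json"))
  tmp <- file.path(out_dir, "results.tsv.tmp")
  utils::write.table(res, tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  file.rename(tmp, file.path(out_dir, "results.tsv"))
  say("wrote ", file.path(out_dir, "results.tsv"))
  res
}

#' Simulate a complete on-disk dataset
#'
#' Writes, for each trial: the two source-story WAVs, the chimera WAV,
#' a phoneme alignment TSV, the simulated EEG container, and a
#' ground-truth JSON -- everything [run_pipeline()] needs.
#'
#' @param config A [simulation_config].
#' @param out_dir Output directory.
#' @param n_bands Chimera band counts to synthesize (default `c(1)`).
#' @param env_bands,env_range Envelope extraction settings used for the
#'   EEG-generating envelope.
#' @return The [trial_manifest] (with `env_wavs`/`tfs_wavs` attributes),
#'   invisibly written to `<out_dir>/manifest.tsv`.
#' @export
simulate_dataset <- function(config, out_dir, n_bands = 1L,
                             env_bands = 32L, env_range = c(80, 3800)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lagspec <- lag_spec(rate = config$eeg_rate)
  kern <- make_trf_kernel(config$kernel_peak_ms, config$kernel_width_ms,
                          config$n_channels, lagspec,
                          seed = sub_seed(config$seed, 91L))
  rows <- list(); env_wavs <- character(); tfs_wavs <- character()
  for (nb in n_bands) {
    for (tr in seq_len(config$n_trials)) {
      tseed <- sub_seed(config$seed, nb * 1000L + tr)
      pair <- make_speech_like_pair(config, seed = tseed)
      ch <- make_chimera(pair$a, pair$b, chimera_spec(
        nb, filterbank_spec(nb, config$carrier_band[1L],
                            config$carrier_band[2L])))
      stim <- normalize_rms(ch$audio, 0.1)
      id <- sprintf("%02dband_t%02d", nb, tr)
      wav_e <- file.path(out_dir, paste0(id, "_env_source.wav"))
      wav_t <- file.path(out_dir, paste0(id, "_tfs_source.wav"))
      wav_c <- file.path(out_dir, paste0(id, "_chimera.wav"))
      write_wav(normalize_rms(pair$a, 0.1), wav_e)
      write_wav(normalize_rms(pair$b, 0.1), wav_t)
      write_wav(stim, wav_c)
      fs <- broadband_envelope(pair$a, n_bands = env_bands,
                               f_low = env_range[1L],
                               f_high = env_range[2L],
                               out_rate = config$eeg_rate)
      eeg <- simulate_eeg(list(fs), kern, lagspec, config$snr_db,
                          config$noise_exponent,
                          seed = sub_seed(tseed, 7L))[[1L]]
      eeg_path <- file.path(out_dir, paste0(id, "_eeg.f32"))
      write_eeg(eeg, eeg_path)
      al <- make_phoneme_sequence(config$trial_duration,
                                  seed = sub_seed(tseed, 13L))
      al_path <- file.path(out_dir, paste0(id, "_phones.tsv"))
      utils::write.table(al, al_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      rows[[length(rows) + 1L]] <- list(trial_id = id, wav = wav_c,
                                        al = al_path, eeg = eeg_path,
                                        nb = nb)
      env_wavs <- c(env_wavs, wav_e)
      tfs_wavs <- c(tfs_wavs, wav_t)
    }
  }
  man <- trial_manifest(
    trial_id = vapply(rows, `[[`, "", "trial_id"),
    stimulus_wav = vapply(rows, `[[`, "", "wav"),
    alignment_file = vapply(rows, `[[`, "", "al"),
    eeg_file = vapply(rows, `[[`, "", "eeg"),
    n_bands = vapply(rows, `[[`, 1L, "nb"))
  attr(man, "env_wavs") <- env_wavs
  attr(man, "tfs_wavs") <- tfs_wavs
  utils::write.table(cbind(man, env_wav = env_wavs, tfs_wav = tfs_wavs),
                     file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gt <- list(kernel_peak_ms = config$kernel_peak_ms,
             kernel_width_ms = config$kernel_width_ms,
             topography = attr(kern, "topography"),
             snr_db = config$snr_db, seed = config$seed)
  write_atomic(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "ground_truth.json"))
  invisible(man)
}
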