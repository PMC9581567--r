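test_that("feature_series enforces its invariants", {
  expect_error(feature_series(matrix(c(1, NA), 1), 128), "finite")
  expect_error(feature_series(matrix(c(0, 2), 1), 128, "phonemes"),
               "binary")
  expect_error(feature_series(matrix(1, 2, 3), 128, "phonemes"),
               "mutually exclusive")
  fs <- feature_series(1:10, 128, "env")
  expect_equal(nrow(fs$values), 1L)
})

test_that("broadband envelope tracks amplitude modulation", {
  rate <- 8000
  n <- rate * 4
  t <- (0:(n - 1)) / rate
  set.seed(1)
  x <- pink_noise(n, rate) * (1 + 0.5 * cos(2 * pi * 4 * t))
  env <- broadband_envelope(audio_signal(x, rate), n_bands = 32,
                            f_low = 80, f_high = 3800, out_rate = 128)
  v <- env$values[1, ] - mean(env$values[1, ])
  A <- Mod(fft(v))[1:(length(v) %/% 2)]
  f <- (seq_along(A) - 1) * 128 / length(v)
  mod_peak <- f[f > 0.5 & f < 20][which.max(A[f > 0.5 & f < 20])]
  expect_equal(mod_peak, 4, tolerance = 0.3)
})

test_that("unmodulated noise yields a nearly constant envelope", {
  rate <- 8000
  set.seed(2)
  x <- audio_signal(pink_noise(rate * 4, rate), rate)
  env <- broadband_envelope(x, n_bands = 32, f_low = 80, f_high = 3800,
                            out_rate = 64)
  v <- env$values[1, 20:(64 * 4 - 20)]
  expect_lt(sd(v) / mean(v), 0.2)
})

test_that("envelope is invariant to polarity flip and floors silence in dB", {
  rate <- 8000
  x <- mk_noise(rate * 2, rate, 3)
  e1 <- broadband_envelope(x, 16, 80, 3800, out_rate = 64)
  e2 <- broadband_envelope(audio_signal(-x$samples, rate), 16, 80, 3800,
                           out_rate = 64)
  expect_equal(e1$values, e2$values, tolerance = 1e-10)
  sil <- audio_signal(numeric(rate * 2), rate)
  edb <- broadband_envelope(sil, 16, 80, 3800, db = TRUE, eps = 1e-6,
                            out_rate = 64)
  expect_lt(max(abs(edb$values + 120)), 0.1)
  expect_error(broadband_envelope(sil, 16, 80, 3800, db = TRUE, eps = 0,
                                  out_rate = 64), "log of zero")
})

test_that("recovered envelope of a pure tone is ~unit (bank sums to one)", {
  rate <- 8000
  t <- (0:(rate * 2 - 1)) / rate
  s <- audio_signal(0.3 * sin(2 * pi * 500 * t), rate)
  re <- recovered_envelope(s, n_bands = 16, f_low = 80, f_high = 3800,
                           out_rate = 64)
  core <- 10:(64 * 2 - 10)
  # TFS is a unit sinusoid; summed per-band magnitudes ~ summed responses
  expect_lt(sd(re$values[1, core]), 0.1)
  expect_equal(mean(re$values[1, core]), 1, tolerance = 0.15)
})

test_that("recovered envelope differs from the chimera's own envelope", {
  rate <- 24000
  n <- rate * 2
  set.seed(4)
  t <- (0:(n - 1)) / rate
  a <- audio_signal(pink_noise(n, rate) * (1 + 0.8 * sin(2 * pi * 3 * t)),
                    rate)
  b <- audio_signal(pink_noise(n, rate) *
                      (1 + 0.8 * sin(2 * pi * 5 * t + 1)), rate)
  ch <- make_chimera(a, b, chimera_spec(1))$audio
  re <- recovered_envelope(ch, n_bands = 32, out_rate = 64)
  env <- broadband_envelope(ch, n_bands = 32, f_high = 8000,
                            out_rate = 64)
  expect_lt(cor(re$values[1, ], env$values[1, ]), 0.9)
})

test_that("recovered envelope of silence returns zeros with a warning", {
  sil <- audio_signal(numeric(8000), 8000)
  expect_warning(re <- recovered_envelope(sil, 16, 80, 3800,
                                          out_rate = 64), "all-zero")
  expect_true(all(re$values == 0))
})

test_that("log-Mel spectrogram localizes tones and tracks a chirp", {
  rate <- 8000
  n <- rate * 2
  t <- (0:(n - 1)) / rate
  sg <- log_mel_spectrogram(audio_signal(sin(2 * pi * 1000 * t), rate),
                            n_filters = 32, f_low = 124.1, f_high = 3600,
                            out_rate = 64)
  expect_equal(dim(sg$values), c(32L, 128L))
  mel <- build_mel_filterbank(32, 124.1, 3600, rate)
  expect_equal(which.max(rowMeans(sg$values)),
               which.min(abs(mel$centers - 1000)))
  sil <- log_mel_spectrogram(audio_signal(numeric(n), rate), 32, 124.1,
                             3600, out_rate = 64)
  expect_lt(diff(range(sil$values)), 1e-9)
  chirp <- sin(2 * pi * (200 * t + (3000 - 200) / 4 * t^2))
  sgc <- log_mel_spectrogram(audio_signal(chirp, rate), 32, 124.1, 3600,
                             out_rate = 64)
  am <- apply(sgc$values, 2, which.max)
  expect_true(all(diff(am) >= 0))
})

test_that("phoneme matrices honor half-open intervals and exclusivity", {
  pm <- phoneme_matrix(alignment_records("AA", 0, 0.5), rate = 128,
                       duration = 1)
  expect_equal(sum(pm$values["AA", ]), 64)
  expect_equal(dim(pm$values), c(35L, 128L))
  empty <- phoneme_matrix(alignment_records(character(), numeric(),
                                            numeric()),
                          rate = 128, duration = 1)
  expect_true(all(empty$values == 0))
  # random non-overlapping alignment: per-record counts within +/-1
  al <- make_phoneme_sequence(5, seed = 11)
  pm2 <- phoneme_matrix(al, rate = 128, duration = 5)
  expect_true(all(colSums(pm2$values) <= 1))
  total <- sum(pm2$values)
  expected <- sum(round((al$offset - al$onset) * 128))
  expect_lte(abs(total - expected), nrow(al))
})

test_that("phoneme matrix warns on unknown labels and truncation", {
  expect_warning(pm <- phoneme_matrix(
    alignment_records(c("AA", "ZZZ"), c(0, 0.5), c(0.4, 0.6)),
    rate = 128, duration = 1), "outside the inventory")
  expect_equal(sum(pm$values), sum(pm$values["AA", ]))
  expect_warning(phoneme_matrix(alignment_records("AA", 0.5, 1.5),
                                rate = 128, duration = 1), "truncating")
  expect_error(alignment_records(c("AA", "B"), c(0, 0.2), c(0.3, 0.4)),
               "overlap")
})

test_that("modulation ratio separates delta- from theta-dominated series", {
  t <- (0:2559) / 128
  expect_gte(modulation_ratio(1 + sin(2 * pi * 2 * t), rate = 128), 10)
  expect_lte(modulation_ratio(1 + sin(2 * pi * 6 * t), rate = 128), 0.1)
  set.seed(5)
  ratios <- replicate(100, modulation_ratio(rnorm(128 * 20), rate = 128))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
  expect_error(modulation_ratio(rnorm(50), rate = 128), "shorter")
  expect_error(modulation_ratio(rnorm(100), rate = 12), "too low")
})

test_that("alignment readers parse TSV and TextGrid formats", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tonset\toffset", "AA\t0\t0.30", "B\t0.30\t0.50"), p)
  al <- read_alignment_tsv(p)
  expect_equal(al$label, c("AA", "B"))
  expect_equal(al$offset, c(0.3, 0.5))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AA\t0\t0.30", "B\t0.30\t0.50"), p2) # no header
  expect_equal(read_alignment_tsv(p2)$label, c("AA", "B"))
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c('File type = "ooTextFile"', 'Object class = "TextGrid"',
               "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 1",
               "item []:", "item [1]:", 'class = "IntervalTier"',
               'name = "phones"', "xmin = 0", "xmax = 1",
               "intervals: size = 3", "intervals [1]:", "xmin = 0",
               "xmax = 0.3", 'text = "AA"', "intervals [2]:",
               "xmin = 0.3", "xmax = 0.5", 'text = ""',
               "intervals [3]:", "xmin = 0.5", "xmax = 1",
               'text = "B"'), tg)
  altg <- read_alignment_textgrid(tg)
  expect_equal(altg$label, c("AA", "B"))
  expect_equal(altg$onset, c(0, 0.5))
})

test_that("feature series round-trip through labelled text + sidecar", {
  fs <- feature_series(matrix(rnorm(60), 3), 64, "sgram",
                       feature_labels = c("a", "b", "c"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_series(fs, p)
  back <- read_feature_series(p)
  expect_equal(back$values, fs$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$rate, 64)
  expect_equal(back$kind, "sgram")
  expect_error(read_feature_series(withr::local_tempfile()), "sidecar")
})
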