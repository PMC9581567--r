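test_that("lag_spec derives the documented integer lag set", {
  ls <- lag_spec(-100, 500, 128)
  expect_equal(ls$lags, seq.int(round(-100 * 128 / 1000),
                                round(500 * 128 / 1000)))
  expect_error(lag_spec(500, -100))
})

test_that("lag matrix realizes the s(t - tau) convention", {
  # identity lag
  s <- rnorm(30)
  ls0 <- lag_spec(-1, 1, 128)
  ls0$lags <- 0L
  expect_equal(lag_matrix(matrix(s, 1), ls0), matrix(s, ncol = 1))
  # impulse: column for lag tau has its one at k + tau
  k <- 25L
  d <- numeric(50); d[k] <- 1
  ls3 <- lag_spec(-1, 1, 128)
  ls3$lags <- c(-1L, 0L, 1L)
  X <- lag_matrix(matrix(d, 1), ls3)
  expect_equal(which(X[, 1] == 1), k - 1L)
  expect_equal(which(X[, 2] == 1), k)
  expect_equal(which(X[, 3] == 1), k + 1L)
  # feature-major, lag-minor ordering for 2 features x 3 lags
  S <- rbind(1:50, 101:150)
  X2 <- lag_matrix(S, ls3)
  expect_equal(ncol(X2), 6L)
  expect_equal(X2[10, 2], S[1, 10])
  expect_equal(X2[10, 5], S[2, 10])
  expect_error(lag_matrix(matrix(rnorm(5), 1), lag_spec(-100, 500, 128)),
               "lag span")
})

test_that("ridge matches the pseudo-inverse oracle and shrinks to zero", {
  set.seed(2)
  X <- matrix(rnorm(600), 100, 6)
  Y <- X %*% rnorm(6) + rnorm(100) * 0.1
  fit <- ridge_fit(X, Y, 0)
  Xi <- cbind(1, X)
  ols <- solve(crossprod(Xi), crossprod(Xi, Y))
  expect_lt(max(abs(c(ols[1], ols[-1]) - c(fit$bias, fit$weights))), 1e-8)
  big <- ridge_fit(scale(X), scale(Y), 1e12)
  expect_lt(sqrt(sum(big$weights^2)), 1e-6)
  # noiseless recovery
  wstar <- rnorm(6)
  fit2 <- ridge_fit(X, X %*% wstar, 1e-6)
  expect_lt(max(abs(fit2$weights - wstar)), 1e-3)
  # rank-deficient with lambda = 0 -> minimum-norm with warning
  Xr <- cbind(X, X[, 1])
  expect_warning(ridge_fit(Xr, Y, 0), "minimum-norm")
  expect_error(ridge_fit(X, Y, -1))
})

test_that("noiseless simulations are recovered almost perfectly", {
  sim <- mk_sim_trials(M = 5, dur = 60, nch = 4, snr_db = 200,
                       width_ms = 20, seed = 1)
  cvf <- nested_cv(sim$trials, "forward", sim$lagspec,
                   lambda_grid = c(1e-6, 1e-2))
  cvb <- nested_cv(sim$trials, "backward", sim$lagspec,
                   lambda_grid = c(1e-6, 1e-2))
  expect_gte(cvf$mean_score, 0.99)
  expect_gte(cvb$mean_score, 0.99)
  # recovered forward kernel matches the generator exactly
  expect_gt(cor(cvf$model$weights[, 1, 1], sim$kern[, 1, 1]), 0.999)
})

test_that("forward and backward agree on noiseless single-channel data", {
  sim <- mk_sim_trials(M = 5, dur = 60, nch = 1, snr_db = 200,
                       width_ms = 20, seed = 3)
  rf <- nested_cv(sim$trials, "forward", sim$lagspec,
                  lambda_grid = 1e-4)$mean_score
  rb <- nested_cv(sim$trials, "backward", sim$lagspec,
                  lambda_grid = 1e-4)$mean_score
  expect_lt(abs(rf - rb), 0.01)
})

test_that("a single-lambda grid is selected verbatim", {
  sim <- mk_sim_trials(M = 3, dur = 10, nch = 2, snr_db = 10, seed = 4)
  cv <- nested_cv(sim$trials, "forward", sim$lagspec, lambda_grid = 42)
  expect_identical(cv$optimal_lambda, 42)
  expect_error(nested_cv(sim$trials[1:2], "forward", sim$lagspec),
               "at least 3")
})

test_that("validation curves are deterministic across runs", {
  sim <- mk_sim_trials(M = 4, dur = 10, nch = 2, snr_db = 5, seed = 5)
  c1 <- nested_cv(sim$trials, "backward", sim$lagspec, 10^(0:3))
  c2 <- nested_cv(sim$trials, "backward", sim$lagspec, 10^(0:3))
  expect_identical(c1$validation_curve, c2$validation_curve)
  expect_identical(c1$per_trial_scores, c2$per_trial_scores)
})

test_that("test scores degrade monotonically as noise increases", {
  snrs <- c(20, 5, -5, -20)
  mean_r <- vapply(seq_along(snrs), function(i) {
    mean(vapply(1:5, function(s) {
      sim <- mk_sim_trials(M = 4, dur = 10, nch = 2, snr_db = snrs[i],
                           seed = 100 * s + i)
      nested_cv(sim$trials, "backward", sim$lagspec,
                lambda_grid = c(1, 100))$mean_score
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(seq_along(snrs), mean_r, method = "spearman"), 0)
  expect_true(all(diff(mean_r) < 0))
})

test_that("forward prediction is the lagged convolution plus bias", {
  ls <- lag_spec(-100, 400, 64)
  kern <- make_trf_kernel(120, 40, 3, ls, seed = 6)
  mdl <- trf_model(kern, bias = c(1, 2, 3), lagspec = ls)
  # zero weights -> bias everywhere
  z <- trf_model(kern * 0, bias = c(1, 2, 3), lagspec = ls)
  pz <- predict_forward(z, feature_series(rnorm(100), 64, "env"))
  expect_equal(unname(pz[10, ]), c(1, 2, 3))
  # impulse feature -> a copy of the kernel at the impulse (system identity)
  d <- numeric(200); d[100] <- 1
  p <- predict_forward(mdl, feature_series(d, 64, "env"))
  lagset <- ls$lags
  expect_equal(p[100 + lagset, 1] - 1, kern[, 1, 1], tolerance = 1e-10,
               ignore_attr = TRUE)
  # linearity
  s1 <- rnorm(150); s2 <- rnorm(150)
  pa <- predict_forward(mdl, feature_series(2 * s1 + 3 * s2, 64, "env"))
  pb <- 2 * predict_forward(mdl, feature_series(s1, 64, "env")) +
    3 * predict_forward(mdl, feature_series(s2, 64, "env")) -
    sweep(matrix(0, 150, 3), 2, (2 + 3 - 1) * mdl$bias, `+`)
  expect_equal(pa, pb, tolerance = 1e-8)
  expect_error(predict_forward(mdl, feature_series(matrix(rnorm(200), 2),
                                                   64, "sgram")),
               "feature count")
})

test_that("decoder honors the anti-causal R(t + tau) convention", {
  rate <- 64
  set.seed(7)
  env <- chimeratrf:::speech_like_envelope(rate * 30, rate, c(1, 8))
  # single channel IS the envelope delayed by +100 ms (~6 samples)
  delay <- round(0.1 * rate)
  eegd <- c(numeric(delay), env[1:(length(env) - delay)])
  tr <- function(tmin, tmax) {
    ls <- lag_spec(tmin, tmax, rate)
    lapply(1:3, function(i) {
      i0 <- (i - 1) * 600 + 1
      list(features = feature_series(env[i0:(i0 + 599)], rate, "env"),
           eeg = eeg_recording(matrix(eegd[i0:(i0 + 599)], 1), rate))
    })
  }
  good <- nested_cv(tr(0, 500), "backward", lag_spec(0, 500, rate),
                    lambda_grid = 1e-6)$mean_score
  bad <- nested_cv(tr(-500, -200), "backward", lag_spec(-500, -200, rate),
                   lambda_grid = 1e-6)$mean_score
  expect_gte(good, 0.95)
  expect_lt(bad, 0.5)
})

test_that("reconstruction from an identity channel is exact", {
  rate <- 64
  set.seed(8)
  env <- chimeratrf:::speech_like_envelope(rate * 10, rate, c(1, 8))
  ls <- lag_spec(-100, 100, rate)
  nlg <- length(ls$lags)
  g <- matrix(0, 1, nlg)
  g[1, which(ls$lags == 0)] <- 1
  dec <- decoder_model(g, bias = 0, lagspec = ls)
  rec <- reconstruct_stimulus(dec, eeg_recording(matrix(env, 1), rate))
  core <- 20:(length(env) - 20)
  expect_gte(cor(rec[core], env[core]), 0.99)
  # zero EEG -> constant bias
  dec2 <- decoder_model(g, bias = 5, lagspec = ls)
  expect_equal(unique(reconstruct_stimulus(
    dec2, eeg_recording(matrix(0, 1, 100), rate))), 5)
  expect_error(reconstruct_stimulus(dec,
                                    eeg_recording(matrix(0, 2, 100),
                                                  rate)),
               "channel count")
})

test_that("decoder weights transform into interpretable forward patterns", {
  ls <- lag_spec(-100, 100, 64)
  g <- matrix(rnorm(3 * length(ls$lags)), 3)
  dec <- decoder_model(g, 0, ls)
  # identity covariance: pattern proportional to the weights
  p1 <- decoder_forward_pattern(dec, diag(3), 2)
  expect_equal(p1, g / 2, ignore_attr = TRUE)
  # two perfectly correlated channels, decoder loads only one
  g2 <- matrix(0, 2, length(ls$lags))
  g2[1, ] <- rnorm(length(ls$lags))
  C <- matrix(1, 2, 2)
  p2 <- decoder_forward_pattern(decoder_model(g2, 0, ls), C, 1)
  expect_equal(p2[1, ], p2[2, ], ignore_attr = TRUE)
  expect_error(decoder_forward_pattern(dec, diag(3), 0), "positive")
  expect_error(decoder_forward_pattern(dec, matrix(1:9, 3), 1),
               "symmetric")
})

test_that("pattern of a decoded forward simulation recovers the topography", {
  sim <- mk_sim_trials(M = 5, dur = 30, nch = 6, snr_db = 20,
                       width_ms = 40, seed = 9)
  cv <- nested_cv(sim$trials, "backward", sim$lagspec,
                  lambda_grid = 10^(0:4), return_predictions = TRUE)
  eeg_all <- do.call(cbind, lapply(sim$eegs, function(e) e$data))
  C <- stats::cov(t(eeg_all))
  rec <- unlist(cv$predictions)
  pat <- decoder_forward_pattern(cv$model, C, stats::var(rec))
  # channel loading at the kernel's peak lag matches the topography
  topo <- attr(sim$kern, "topography")
  peak_col <- which.max(abs(colSums(pat * topo)))
  v <- pat[, peak_col]
  cosim <- abs(sum(v * topo)) / sqrt(sum(v^2) * sum(topo^2))
  expect_gte(cosim, 0.95)
})

test_that("band-pass filtering is selective, zero-phase and idempotent", {
  rate <- 128
  t <- (0:(rate * 20 - 1)) / rate
  core <- 1000:1500
  e6 <- eeg_recording(matrix(sin(2 * pi * 6 * t), 1), rate)
  in_band <- bandpass_eeg(e6, c(4, 8))
  expect_gte(max(abs(in_band$data[1, core])), 0.9)
  # zero phase: filtered 6 Hz stays aligned with the input
  expect_gte(cor(in_band$data[1, core], e6$data[1, core]), 0.99)
  out_band <- suppressWarnings(bandpass_eeg(e6, c(1, 4)))
  expect_lte(max(abs(out_band$data[1, core])), 0.1)
  twice <- bandpass_eeg(in_band, c(4, 8))
  expect_lt(max(abs(twice$data[1, core] - in_band$data[1, core])) /
              max(abs(in_band$data[1, core])), 0.01)
  expect_error(bandpass_eeg(e6, c(4, 100)), "rate/2")
})
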