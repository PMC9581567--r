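#' EEG recording container
#'
#' @param data Numeric matrix `n_channels x n_samples` (microvolts).
#' @param rate Sampling rate in Hz (128 by default downstream).
#' @param channel_names Optional character vector of channel names.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (rate <= 0) stop("`rate` must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match the number of rows")
  structure(list(data = data, rate = rate, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Stimulus-response lag specification
#'
#' Lags follow the forward-model convention: the response at time t is
#' modeled from the stimulus at t - tau for every tau between `t_min` and
#' `t_max`. Positive lags therefore look back at past stimulus samples;
#' the canonical analysis window is -100 to +500 ms.
#'
#' @param t_min,t_max Lag window in milliseconds, `t_min < t_max`.
#' @param rate Sampling rate (Hz) the lags are realized at.
#' @return A `lag_spec` with integer sample offsets `lags` covering
#'   `round(t_min*rate/1000)` to `round(t_max*rate/1000)` inclusive.
#' @export
lag_spec <- function(t_min = -100, t_max = 500, rate = 128) {
  if (t_min >= t_max) stop("need t_min < t_max")
  lags <- seq.int(round(t_min * rate / 1000), round(t_max * rate / 1000))
  structure(list(t_min = t_min, t_max = t_max, rate = rate, lags = lags,
                 lag_ms = lags * 1000 / rate),
            class = "lag_spec")
}

#' Lagged design matrix
#'
#' Column (f, tau) holds feature f delayed by tau samples
#' (`X[t, ] = s[t - tau]`), zero-padded at the edges. Columns are ordered
#' feature-major, lag-minor: all lags of feature 1, then all lags of
#' feature 2, and so on.
#'
#' @param series A [feature_series] (or numeric matrix
#'   `n_features x n_samples`).
#' @param lagspec A [lag_spec]; its rate must match the series rate.
#' @return Numeric matrix `n_samples x (n_features * n_lags)`.
#' @export
lag_matrix <- function(series, lagspec) {
  if (inherits(series, "feature_series")) {
    if (!isTRUE(all.equal(series$rate, lagspec$rate)))
      stop("series rate does not match lag_spec rate")
    S <- series$values
  } else S <- if (is.vector(series)) matrix(series, nrow = 1L) else series
  n <- ncol(S)
  lags <- lagspec$lags
  if (max(lags) - min(lags) >= n)
    stop("lag span equals or exceeds the series length")
  nf <- nrow(S); nl <- length(lags)
  X <- matrix(0, n, nf * nl)
  t_idx <- seq_len(n)
  for (f in seq_len(nf)) {
    for (j in seq_len(nl)) {
      src <- t_idx - lags[j]
      ok <- src >= 1L & src <= n
      X[t_idx[ok], (f - 1L) * nl + j] <- S[f, src[ok]]
    }
  }
  X
}

#' Ridge regression with unpenalized intercept
#'
#' Minimizes `||Y - Xw - b||^2 + lambda ||w||^2`; the intercept is handled
#' by centering and never penalized. With `lambda = 0` and a
#' rank-deficient design the minimum-norm least-squares solution is
#' returned with a warning.
#'
#' @param X Design matrix `n x p`.
#' @param Y Response vector or matrix `n x q`.
#' @param lambda Nonnegative ridge penalty.
#' @return List with `weights` (`p x q`) and `bias` (length `q`).
#' @export
ridge_fit <- function(X, Y, lambda) {
  if (lambda < 0) stop("`lambda` must be nonnegative")
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm)
  Yc <- sweep(Y, 2L, ym)
  XtX <- crossprod(Xc)
  e <- eigen(XtX, symmetric = TRUE)
  d <- e$values
  if (lambda == 0 && min(d) < max(d, 1) * 1e-10) {
    warning("rank-deficient design with lambda = 0; ",
            "returning the minimum-norm solution")
    inv_d <- ifelse(d > max(d, 1) * 1e-10, 1 / d, 0)
  } else inv_d <- 1 / (d + lambda)
  W <- e$vectors %*% (inv_d * crossprod(e$vectors, crossprod(Xc, Yc)))
  list(weights = W, bias = as.numeric(ym - crossprod(W, xm)))
}

# Assemble (X, Y) for one trial given the modeling direction.
trial_design <- function(trial, direction, lagspec) {
  fs <- trial$features; eeg <- trial$eeg
  if (!isTRUE(all.equal(fs$rate, eeg$rate)))
    stop("feature and EEG rates differ within a trial")
  if (direction == "forward") {
    list(X = lag_matrix(fs, lagspec), Y = t(eeg$data))
  } else {
    # backward: reconstruct the (univariate) feature from EEG that FOLLOWS
    # the stimulus sample -- mirror the lag window (s(t) ~ r(t + tau))
    if (nrow(fs$values) != 1L)
      stop("backward decoding requires a univariate feature")
    mspec <- lagspec
    mspec$lags <- -rev(lagspec$lags)
    list(X = lag_matrix(eeg$data, mspec), Y = matrix(fs$values[1L, ],
                                                     ncol = 1L))
  }
}

#' Nested leave-one-out cross-validated TRF fitting
#'
#' Implements the double leave-one-out scheme: a separate model is fit to
#' every trial for every lambda on the grid; for each outer test trial the
#' remaining M-1 trials host an inner loop in which each trial in turn
#' serves as validation set while the single-trial models of the others
#' are averaged (weight averaging, not refitting) and scored on it with
#' Pearson's r. The lambda with the best mean inner-validation score is
#' selected; the models of all M-1 non-test trials are then averaged at
#' that lambda and scored on the held-out test trial.
#'
#' @param trials List of trials, each a list with elements `features`
#'   (a [feature_series]) and `eeg` (an [eeg_recording]); at least 3.
#' @param direction `"forward"` (predict EEG from features) or
#'   `"backward"` (reconstruct a univariate feature from all channels).
#' @param lagspec A [lag_spec].
#' @param lambda_grid Ridge penalties to search (default `10^(0:8)`).
#' @param scoring_channels Optional integer/character subset of channels
#'   over which forward-model scores are averaged (default: all).
#' @param return_predictions Keep each held-out trial's prediction?
#' @return A `trf_cv` object: `optimal_lambda`, `lambda_grid`,
#'   `validation_curve` (mean inner score per lambda), `per_trial_scores`
#'   (the M test-trial scores), `mean_score`, `per_trial_lambda`, `model`
#'   (single-trial models averaged across all M trials at the optimal
#'   lambda, as a [trf_model]/[decoder_model]), and optionally
#'   `predictions`.
#' @export
nested_cv <- function(trials, direction = c("forward", "backward"),
                      lagspec = lag_spec(), lambda_grid = 10^(0:8),
                      scoring_channels = NULL,
                      return_predictions = FALSE) {
  direction <- match.arg(direction)
  problem <- cv_problem(trials, direction, lagspec, scoring_channels)
  fit <- cv_engine(problem, seq_along(trials), lambda_grid,
                   return_predictions = return_predictions)
  wrap_cv_result(problem, fit, lambda_grid)
}

# Precompute everything that does not depend on the feature/response
# pairing: per-trial centered designs with their eigendecompositions, and
# per-trial centered responses.  Trial-shuffle permutations then reuse all
# of it.
cv_problem <- function(trials, direction, lagspec,
                       scoring_channels = NULL) {
  M <- length(trials)
  if (M < 3L) stop("nested cross-validation needs at least 3 trials")
  designs <- lapply(trials, trial_design, direction = direction,
                    lagspec = lagspec)
  ch_names <- trials[[1L]]$eeg$channel_names
  sc_idx <- NULL
  if (direction == "forward") {
    sc_idx <- if (is.null(scoring_channels)) seq_along(ch_names)
              else if (is.character(scoring_channels))
                match(scoring_channels, ch_names)
              else as.integer(scoring_channels)
    if (anyNA(sc_idx)) stop("unknown scoring channel")
  }
  fe <- lapply(designs, function(d) {
    xm <- colMeans(d$X)
    Xc <- sweep(d$X, 2L, xm)
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    list(xm = xm, Xc = Xc, V = e$vectors, d = e$values)
  })
  ys <- lapply(designs, function(d) {
    ym <- colMeans(d$Y)
    list(ym = ym, Yc = sweep(d$Y, 2L, ym))
  })
  list(M = M, direction = direction, lagspec = lagspec, fe = fe, ys = ys,
       sc_idx = sc_idx, ch_names = ch_names,
       n_features = if (direction == "forward")
         ncol(designs[[1L]]$X) / length(lagspec$lags) else 1L)
}

# Run the double leave-one-out for a given feature->response pairing:
# trial i's features are paired with the responses of trial pairing[i].
cv_engine <- function(problem, pairing, lambda_grid,
                      return_predictions = FALSE) {
  M <- problem$M
  nl <- length(lambda_grid)
  fe <- problem$fe; ys <- problem$ys
  models <- vector("list", M)
  for (i in seq_len(M)) {
    yy <- ys[[pairing[i]]]
    VtXtY <- crossprod(fe[[i]]$V, crossprod(fe[[i]]$Xc, yy$Yc))
    models[[i]] <- lapply(lambda_grid, function(l) {
      W <- fe[[i]]$V %*% (VtXtY / (fe[[i]]$d + l))
      list(weights = W, bias = as.numeric(yy$ym - crossprod(W,
                                                            fe[[i]]$xm)))
    })
  }
  sumW <- lapply(seq_len(nl), function(l)
    Reduce(`+`, lapply(models, function(m) m[[l]]$weights)))
  sumB <- lapply(seq_len(nl), function(l)
    Reduce(`+`, lapply(models, function(m) m[[l]]$bias)))
  avg_model <- function(excl, l) {
    W <- sumW[[l]]; b <- sumB[[l]]
    for (i in excl) {
      W <- W - models[[i]][[l]]$weights
      b <- b - models[[i]][[l]]$bias
    }
    k <- M - length(excl)
    list(weights = W / k, bias = b / k)
  }
  score_on <- function(mod, i) {
    P <- fe[[i]]$Xc %*% mod$weights
    r <- col_pearson_centered(P, ys[[pairing[i]]]$Yc)
    if (!all(is.finite(r))) stop("non-finite validation score")
    if (problem$direction == "forward") mean(r[problem$sc_idx])
    else r[1L]
  }
  per_trial_scores <- numeric(M)
  per_trial_lambda_idx <- integer(M)
  curve_sum <- numeric(nl)
  predictions <- if (return_predictions) vector("list", M) else NULL
  for (m in seq_len(M)) {
    inner <- setdiff(seq_len(M), m)
    val_scores <- matrix(0, length(inner), nl)
    for (vi in seq_along(inner)) {
      v <- inner[vi]
      for (l in seq_len(nl))
        val_scores[vi, l] <- score_on(avg_model(c(m, v), l), v)
    }
    curve <- colMeans(val_scores)
    l_star <- which.max(curve)
    per_trial_lambda_idx[m] <- l_star
    curve_sum <- curve_sum + curve
    final <- avg_model(m, l_star)
    per_trial_scores[m] <- score_on(final, m)
    if (return_predictions) {
      P <- fe[[m]]$Xc %*% final$weights
      # add back the prediction mean implied by the raw design and bias
      offset <- crossprod(fe[[m]]$xm, final$weights) + final$bias
      predictions[[m]] <- sweep(P, 2L, as.numeric(offset), `+`)
    }
  }
  validation_curve <- curve_sum / M
  opt_idx <- which.max(validation_curve)
  list(per_trial_scores = per_trial_scores,
       per_trial_lambda_idx = per_trial_lambda_idx,
       validation_curve = validation_curve, opt_idx = opt_idx,
       mean_score = mean(per_trial_scores),
       full_model = avg_model(integer(0), opt_idx),
       predictions = predictions)
}

wrap_cv_result <- function(problem, fit, lambda_grid) {
  lagspec <- problem$lagspec
  nlg <- length(lagspec$lags)
  full <- fit$full_model
  model <- if (problem$direction == "forward") {
    trf_model(array(full$weights,
                    dim = c(nlg, problem$n_features,
                            ncol(full$weights))),
              bias = full$bias, lagspec = lagspec,
              lambda = lambda_grid[fit$opt_idx])
  } else {
    g_desc <- matrix(full$weights, nrow = length(problem$ch_names),
                     ncol = nlg, byrow = TRUE)
    decoder_model(g_desc[, rev(seq_len(nlg)), drop = FALSE],
                  bias = full$bias, lagspec = lagspec,
                  lambda = lambda_grid[fit$opt_idx],
                  channel_names = problem$ch_names)
  }
  structure(list(optimal_lambda = lambda_grid[fit$opt_idx],
                 lambda_grid = lambda_grid,
                 validation_curve = fit$validation_curve,
                 per_trial_scores = fit$per_trial_scores,
                 per_trial_lambda =
                   lambda_grid[fit$per_trial_lambda_idx],
                 mean_score = fit$mean_score,
                 direction = problem$direction, model = model,
                 predictions = fit$predictions),
            class = "trf_cv")
}

col_pearson_centered <- function(A, B) {
  # columnwise Pearson r for already column-centered matrices
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den == 0, NA_real_, num / den)
}

#' Trial-shuffle permutation null for nested-CV scores
#'
#' Efficient specialization of [permutation_null()] for the nested-CV
#' statistic itself: responses are re-paired with the features of a
#' different trial (derangements) and the identical double leave-one-out
#' pipeline is rerun, reusing the per-trial design decompositions, which
#' do not depend on the pairing.
#'
#' @inheritParams nested_cv
#' @param n_permutations Number of derangements (default 1000).
#' @param seed Integer seed.
#' @return A `null_distribution` (see [permutation_null()]).
#' @export
nested_cv_permutation_null <- function(trials,
                                       direction = c("forward",
                                                     "backward"),
                                       lagspec = lag_spec(),
                                       lambda_grid = 10^(0:8),
                                       scoring_channels = NULL,
                                       n_permutations = 1000L,
                                       seed = 1L) {
  direction <- match.arg(direction)
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  if (length(trials) < 5L)
    stop("permutation testing needs at least 5 trials")
  problem <- cv_problem(trials, direction, lagspec, scoring_channels)
  observed <- cv_engine(problem, seq_len(problem$M),
                        lambda_grid)$mean_score
  scores <- with_seed_(seed, {
    vapply(seq_len(n_permutations), function(k) {
      p <- derangement(problem$M)
      # convention: trial i's features are matched to the EEG of trial
      # p[i]; for backward models the EEG is the design side, so the
      # engine pairing is the inverse permutation
      pairing <- if (direction == "backward") order(p) else p
      cv_engine(problem, pairing, lambda_grid)$mean_score
    }, numeric(1))
  })
  structure(list(scores = scores, observed = observed,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 p_value = (1 + sum(scores >= observed)) /
                   (n_permutations + 1)),
            class = "null_distribution")
}

#' Per-channel unique-contribution permutation null
#'
#' The variance-partitioning analysis with its trial-shuffle null: two
#' forward feature models (target and nuisance) are fit with the nested-CV
#' pipeline, EEG is predicted for every held-out trial, and the per-channel
#' partial correlation between recorded and target-predicted EEG
#' (controlling for the nuisance prediction) is the statistic. Each
#' permutation re-pairs the EEG with the features of a different trial and
#' reruns the whole procedure.
#'
#' @param eeg_trials List of [eeg_recording]s (one per trial).
#' @param target_features,nuisance_features Lists of [feature_series]
#'   (one per trial) for the feature family of interest and the family to
#'   control for.
#' @param lagspec A [lag_spec].
#' @param lambda_grid Ridge penalties to search.
#' @param n_permutations Number of derangements (default 200).
#' @param seed Integer seed.
#' @return List with `observed` (per-channel partial r), `null` (matrix
#'   `n_permutations x n_channels`), `p_values` (per-channel, add-one
#'   convention), and `channel_names`.
#' @export
unique_contribution_null <- function(eeg_trials, target_features,
                                     nuisance_features,
                                     lagspec = lag_spec(),
                                     lambda_grid = 10^(0:8),
                                     n_permutations = 200L, seed = 1L) {
  M <- length(eeg_trials)
  if (M < 5L) stop("permutation testing needs at least 5 trials")
  mk <- function(feats) Map(function(f, e) list(features = f, eeg = e),
                            feats, eeg_trials)
  prob_t <- cv_problem(mk(target_features), "forward", lagspec)
  prob_n <- cv_problem(mk(nuisance_features), "forward", lagspec)
  stat <- function(pairing) {
    pt <- cv_engine(prob_t, pairing, lambda_grid,
                    return_predictions = TRUE)$predictions
    pn <- cv_engine(prob_n, pairing, lambda_grid,
                    return_predictions = TRUE)$predictions
    Y <- do.call(rbind, lapply(seq_len(M), function(i)
      t(eeg_trials[[pairing[i]]]$data)))
    Pt <- do.call(rbind, pt)
    Pn <- do.call(rbind, pn)
    unique_contribution(Y, Pt, Pn)
  }
  observed <- stat(seq_len(M))
  null <- with_seed_(seed, {
    t(vapply(seq_len(n_permutations), function(k)
      stat(derangement(M)), numeric(length(observed))))
  })
  p <- (1 + colSums(sweep(null, 2L, observed, `>=`))) /
    (n_permutations + 1)
  list(observed = observed, null = null, p_values = p,
       channel_names = eeg_trials[[1L]]$channel_names)
}

#' Forward TRF model
#'
#' @param weights Array `n_lags x n_features x n_channels` (or a matrix of
#'   stacked feature-major lagged weights with `feature_major = TRUE`).
#' @param bias Numeric vector, one intercept per channel.
#' @param lagspec A [lag_spec].
#' @param lambda Ridge penalty the weights were fit with.
#' @param feature_major Internal flag; the canonical storage is
#'   `[lag, feature, channel]`.
#' @return A `trf_model` object.
#' @export
trf_model <- function(weights, bias, lagspec, lambda = 0,
                      feature_major = FALSE) {
  if (!all(is.finite(weights))) stop("weights must be finite")
  structure(list(weights = weights, bias = bias, lagspec = lagspec,
                 lambda = lambda),
            class = "trf_model")
}

#' Backward decoder model
#'
#' @param weights Matrix `n_channels x n_lags`.
#' @param bias Scalar intercept.
#' @param lagspec A [lag_spec] (forward-convention lags; the decoder reads
#'   EEG at `t + tau` for each `tau`).
#' @param lambda Ridge penalty.
#' @param channel_names Optional channel names.
#' @return A `decoder_model` object.
#' @export
decoder_model <- function(weights, bias, lagspec, lambda = 0,
                          channel_names = NULL) {
  if (!all(is.finite(weights))) stop("weights must be finite")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(weights)))
  structure(list(weights = weights, bias = bias, lagspec = lagspec,
                 lambda = lambda, channel_names = channel_names),
            class = "decoder_model")
}

#' Predict EEG from stimulus features with a forward model
#'
#' Convolves the features with the TRF weights (`r(t,n) = sum_tau
#' w(tau,n) s(t - tau) + b(n)`); edges are zero-padded so the prediction
#' has the same length as the input.
#'
#' @param model A [trf_model].
#' @param series A [feature_series] with as many features as the model.
#' @return Numeric matrix `n_samples x n_channels`.
#' @export
predict_forward <- function(model, series) {
  w <- model$weights
  if (inherits(series, "feature_series")) {
    if (!isTRUE(all.equal(series$rate, model$lagspec$rate)))
      stop("series rate does not match the model's lag rate")
  }
  S <- if (inherits(series, "feature_series")) series$values
       else if (is.vector(series)) matrix(series, nrow = 1L) else series
  if (dim(w)[2L] != nrow(S))
    stop("feature count does not match the model")
  X <- lag_matrix(S, model$lagspec)
  nlg <- dim(w)[1L]; nf <- dim(w)[2L]; nc <- dim(w)[3L]
  Wm <- matrix(aperm(w, c(1L, 2L, 3L)), nrow = nlg * nf, ncol = nc)
  P <- X %*% Wm
  sweep(P, 2L, model$bias, `+`)
}

#' Reconstruct a stimulus feature from EEG with a backward decoder
#'
#' Honors the anti-causal convention `s_hat(t) = sum_n sum_tau
#' R(t + tau, n) g(tau, n) + b`: the decoder integrates EEG recorded after
#' the stimulus sample (for positive forward lags).
#'
#' @param model A [decoder_model].
#' @param eeg An [eeg_recording] with as many channels as the model.
#' @return Numeric vector of reconstructed feature samples.
#' @export
reconstruct_stimulus <- function(model, eeg) {
  if (nrow(eeg$data) != nrow(model$weights))
    stop("channel count does not match the model")
  if (!isTRUE(all.equal(eeg$rate, model$lagspec$rate)))
    stop("EEG rate does not match the model's lag rate")
  mspec <- model$lagspec
  mspec$lags <- -rev(model$lagspec$lags)
  X <- lag_matrix(eeg$data, mspec)
  # columns are channel-major with lags in mirrored (reversed) order;
  # weights are stored [channel, lag] in forward lag order
  Wv <- as.numeric(t(model$weights[, rev(seq_len(ncol(model$weights))),
                                   drop = FALSE]))
  as.numeric(X %*% Wv + model$bias)
}

#' Transform decoder weights into a forward activation pattern
#'
#' The standard weight-to-pattern transformation for linear backward
#' models: `A = Cov(EEG) %*% G / var(reconstruction)`, giving channel
#' topographies that are interpretable in the same way as forward-model
#' weights.
#'
#' @param model A [decoder_model].
#' @param eeg_covariance Channel covariance matrix of the EEG
#'   (`n_channels x n_channels`, symmetric positive semi-definite).
#' @param reconstruction_variance Variance of the decoder output (> 0).
#' @return Pattern matrix `n_channels x n_lags`.
#' @export
decoder_forward_pattern <- function(model, eeg_covariance,
                                    reconstruction_variance) {
  C <- as.matrix(eeg_covariance)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(abs(C), 1))
    stop("`eeg_covariance` must be a symmetric matrix")
  if (nrow(C) != nrow(model$weights))
    stop("covariance dimension does not match the decoder")
  if (!is.finite(reconstruction_variance) || reconstruction_variance <= 0)
    stop("`reconstruction_variance` must be a positive number")
  (C %*% model$weights) / reconstruction_variance
}

#' Zero-phase band-pass filter an EEG recording
#'
#' Chebyshev type 2 band-pass (stop-band attenuation 40 dB, stop-band
#' edges placed half an octave outside the requested pass-band) applied
#' forward-backward for zero phase shift. If the IIR design is unstable at
#' extreme band edges, a high-order zero-phase FIR is used instead with a
#' warning.
#'
#' @param eeg An [eeg_recording].
#' @param band Length-2 numeric vector, pass-band in Hz.
#' @param order IIR order (default 6).
#' @return Filtered [eeg_recording].
#' @export
bandpass_eeg <- function(eeg, band, order = 6L) {
  if (!(band[1L] > 0 && band[2L] > band[1L] && band[2L] < eeg$rate / 2))
    stop("`band` must satisfy 0 < low < high < rate/2")
  nyq <- eeg$rate / 2
  stop_lo <- band[1L] / sqrt(2)
  stop_hi <- min(band[2L] * sqrt(2), 0.99 * nyq)
  flt <- NULL
  stable <- FALSE
  for (ord in seq(order, 3L)) {
    cand <- signal::cheby2(ord, 40, c(stop_lo, stop_hi) / nyq,
                           type = "pass")
    if (all(Mod(polyroot(rev(cand$a))) < 1 - 1e-8)) {
      flt <- cand; stable <- TRUE; break
    }
  }
  out <- eeg$data
  if (stable) {
    for (k in seq_len(nrow(out)))
      out[k, ] <- signal::filtfilt(flt, eeg$data[k, ])
  } else {
    warning("unstable IIR design at these band edges; ",
            "falling back to a zero-phase FIR band-pass")
    for (k in seq_len(nrow(out))) {
      lo <- fir_lowpass_zerophase(eeg$data[k, ], band[2L], eeg$rate)
      out[k, ] <- lo - fir_lowpass_zerophase(lo, band[1L], eeg$rate)
    }
  }
  eeg_recording(out, eeg$rate, eeg$channel_names)
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf(
    "<trf_cv:%s> %d trial(s); optimal lambda = %g; mean test r = %.4f\n",
    x$direction, length(x$per_trial_scores), x$optimal_lambda,
    x$mean_score))
  invisible(x)
}
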