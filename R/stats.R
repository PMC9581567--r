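#' Pearson correlation score
#'
#' Plain Pearson's r with explicit guards: equal lengths of at least 3 and
#' nonzero variance in both inputs (a zero-variance input is an error, not
#' an NaN).
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_score <- function(a, b) {
  if (length(a) != length(b)) stop("inputs differ in length")
  if (length(a) < 3L) stop("need at least 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input to pearson_score")
  stats::cor(a, b)
}

#' Partial correlation controlling for covariates
#'
#' Correlation between the residuals of `x` and `y` after each is linearly
#' regressed (with intercept) on the columns of `z`. With `z = NULL` this
#' is exactly the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param z Optional numeric vector or matrix of covariates (columns).
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z = NULL) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (is.null(z)) return(pearson_score(x, y))
  Z <- if (is.vector(z)) matrix(z, ncol = 1L) else as.matrix(z)
  if (nrow(Z) != length(x)) stop("z rows must match the series length")
  Zi <- cbind(1, Z)
  rx <- stats::lm.fit(Zi, x)$residuals
  ry <- stats::lm.fit(Zi, y)$residuals
  tol <- 1e-12
  if (stats::var(rx) <= tol * max(stats::var(x), 1) ||
      stats::var(ry) <= tol * max(stats::var(y), 1))
    stop("covariates are collinear with x or y; ",
         "partial correlation undefined")
  stats::cor(rx, ry)
}

#' Unique predictive contribution of one encoding model
#'
#' For each channel, the partial correlation between the recorded EEG and
#' the EEG predicted by the model of interest, controlling for the EEG
#' predicted by the nuisance model(s). This isolates the variance a
#' feature family explains over and above its competitors.
#'
#' @param eeg An [eeg_recording] or `n_samples x n_channels` matrix of
#'   recorded EEG.
#' @param pred_target `n_samples x n_channels` matrix of EEG predicted by
#'   the model of interest.
#' @param pred_nuisance Matrix (or list of matrices) of EEG predicted by
#'   the model(s) to control for.
#' @param channels Optional subset of channel indices to return/average.
#' @param average Average the per-channel partial correlations?
#' @return Named numeric vector of per-channel partial r (or a scalar
#'   mean when `average = TRUE`).
#' @export
unique_contribution <- function(eeg, pred_target, pred_nuisance,
                                channels = NULL, average = FALSE) {
  Y <- if (inherits(eeg, "eeg_recording")) t(eeg$data) else as.matrix(eeg)
  nuis <- if (is.list(pred_nuisance)) pred_nuisance else list(pred_nuisance)
  nc <- ncol(Y)
  if (ncol(pred_target) != nc ||
      any(vapply(nuis, ncol, 1L) != nc))
    stop("channel counts differ between EEG and predictions")
  if (is.null(channels)) channels <- seq_len(nc)
  r <- vapply(channels, function(ch) {
    Z <- do.call(cbind, lapply(nuis, function(m) m[, ch]))
    partial_correlation(Y[, ch], pred_target[, ch], Z)
  }, numeric(1))
  names(r) <- if (inherits(eeg, "eeg_recording"))
    eeg$channel_names[channels] else paste0("ch", channels)
  if (average) mean(r) else r
}

# Uniform random derangement (permutation with no fixed points) of 1..n.
derangement <- function(n) {
  if (n < 2L) stop("a derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Trial-shuffle permutation null distribution
#'
#' Re-pairs neural responses with the stimulus features of a *different*
#' trial (a derangement, so no trial keeps its own features), reruns the
#' identical model-fitting pipeline, and records the resulting score. The
#' p-value uses the add-one convention
#' `(1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param trials List of trials as for [nested_cv()] (>= 5).
#' @param model_fitter Function taking a re-paired trial list and
#'   returning a scalar score; use the same procedure that produced the
#'   observed statistic.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed; the null is reproducible given it.
#' @param observed Optional precomputed observed score; computed from the
#'   unpermuted trials when missing.
#' @return A `null_distribution` with `scores`, `observed`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_null <- function(trials, model_fitter, n_permutations = 1000L,
                             seed = 1L, observed = NULL) {
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  if (length(trials) < 5L)
    stop("permutation testing needs at least 5 trials")
  if (is.null(observed)) observed <- model_fitter(trials)
  M <- length(trials)
  scores <- numeric(n_permutations)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (k in seq_len(n_permutations)) {
    p <- derangement(M)
    permuted <- lapply(seq_len(M), function(i)
      list(features = trials[[i]]$features, eeg = trials[[p[i]]]$eeg))
    scores[k] <- model_fitter(permuted)
  }
  structure(list(scores = scores, observed = observed,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 p_value = (1 + sum(scores >= observed)) /
                   (n_permutations + 1)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> observed %.4f vs %d permutations (null mean %.4f, q95 %.4f), p = %.4g\n",
    x$observed, x$n_permutations, mean(x$scores),
    stats::quantile(x$scores, 0.95), x$p_value))
  invisible(x)
}

#' Binomial chance-level threshold for multiple-choice performance
#'
#' The percentage score at the `1 - alpha` quantile of a
#' Binomial(n_trials, p_chance) score distribution: the smallest integer
#' number of correct answers k whose cumulative probability reaches
#' `1 - alpha`, expressed as `100 * k / n_trials`. Scores above this
#' threshold are unlikely (at level alpha) under guessing.
#'
#' @param n_trials Total number of questions across the group.
#' @param p_chance Per-question guessing probability (e.g. 0.25 for four
#'   alternatives).
#' @param alpha Significance level.
#' @return Threshold as a percentage.
#' @export
chance_threshold <- function(n_trials, p_chance, alpha = 0.05) {
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  if (!(p_chance > 0 && p_chance < 1)) stop("`p_chance` must be in (0,1)")
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0,1)")
  k <- stats::qbinom(1 - alpha, n_trials, p_chance)
  100 * k / n_trials
}

#' Bootstrap correlation with percentile confidence interval
#'
#' Paired resampling with replacement; degenerate resamples (zero
#' variance in either member) are redrawn, up to a cap.
#'
#' @param x,y Numeric vectors of equal length (>= 5).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param method `"pearson"` or `"spearman"`.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `r` (observed), `ci` (percentile interval),
#'   `boot_r`, `n_redrawn`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 1000L,
                                  method = c("pearson", "spearman"),
                                  seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 5L) stop("need at least 5 paired observations")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  boot_r <- numeric(n_boot)
  n_redrawn <- 0L
  for (k in seq_len(n_boot)) {
    for (attempt in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
      if (attempt == 100L) stop("too many degenerate bootstrap resamples")
    }
    boot_r[k] <- stats::cor(x[idx], y[idx], method = method)
  }
  a <- (1 - conf) / 2
  list(r = stats::cor(x, y, method = method),
       ci = unname(stats::quantile(boot_r, c(a, 1 - a))),
       boot_r = boot_r, n_redrawn = n_redrawn)
}

#' Benjamini-Hochberg adjusted p-values across channels
#'
#' Thin convenience wrapper over `p.adjust(..., "BH")` for per-channel
#' permutation p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")
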