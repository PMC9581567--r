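test_that("pearson_score matches the textbook formula and guards inputs", {
  expect_equal(pearson_score(1:10, 1:10), 1)
  expect_equal(pearson_score(1:10, -(1:10)), -1)
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_score(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson_score(1:5, 1:4), "length")
  expect_error(pearson_score(1:2, 1:2), "at least 3")
  expect_error(pearson_score(rep(1, 5), 1:5), "zero-variance")
})

test_that("partial correlation matches its closed form and oracle", {
  # orthogonalized construction: r_xz = r_yz = 0 exactly -> partial = plain
  set.seed(1)
  n <- 400
  z <- rnorm(n)
  rawx <- rnorm(n); rawy <- 0.5 * scale(rawx)[, 1] + sqrt(0.75) * rnorm(n)
  Zi <- cbind(1, z)
  x <- stats::lm.fit(Zi, rawx)$residuals
  y <- stats::lm.fit(Zi, rawy)$residuals
  expect_equal(partial_correlation(x, y, z), pearson_score(x, y),
               tolerance = 1e-10)
  # recursive univariate formula
  set.seed(2)
  x2 <- rnorm(200); z2 <- 0.4 * x2 + rnorm(200)
  y2 <- 0.3 * x2 + 0.3 * z2 + rnorm(200)
  rxy <- cor(x2, y2); rxz <- cor(x2, z2); ryz <- cor(y2, z2)
  expect_equal(partial_correlation(x2, y2, z2),
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-10)
  # residual-regression oracle on random multivariate triples
  for (s in 1:5) {
    set.seed(s + 10)
    Z <- matrix(rnorm(200 * 3), 200)
    x3 <- rnorm(200); y3 <- rnorm(200)
    Zi3 <- cbind(1, Z)
    oracle <- cor(stats::lm.fit(Zi3, x3)$residuals,
                  stats::lm.fit(Zi3, y3)$residuals)
    expect_equal(partial_correlation(x3, y3, Z), oracle,
                 tolerance = 1e-10)
  }
  # no covariates degenerates exactly to pearson
  expect_identical(partial_correlation(x2, y2, NULL),
                   pearson_score(x2, y2))
  # collinear covariate is an error
  expect_error(partial_correlation(x2, y2, x2), "collinear")
})

test_that("an irrelevant covariate leaves the correlation unchanged", {
  set.seed(3)
  diffs <- replicate(100, {
    x <- rnorm(80); y <- 0.5 * x + rnorm(80); z <- rnorm(80)
    partial_correlation(x, y, z) - cor(x, y)
  })
  expect_lt(abs(mean(diffs)), 0.01)
})

test_that("unique_contribution isolates per-channel variance", {
  set.seed(4)
  n <- 500
  pt <- matrix(rnorm(n * 2), n)
  pn <- matrix(rnorm(n * 2), n)
  Y <- 0.6 * pt + 0.6 * pn + matrix(rnorm(n * 2), n)
  r <- unique_contribution(Y, pt, pn)
  expect_length(r, 2L)
  expect_true(all(r > 0.3))
  expect_error(unique_contribution(Y, pt, pt), "collinear")
  expect_equal(unique_contribution(Y, pt, pn, average = TRUE), mean(r))
})

test_that("derangements never keep a trial in place", {
  set.seed(5)
  for (n in c(2, 5, 9)) {
    p <- chimeratrf:::derangement(n)
    expect_true(all(p != seq_len(n)))
    expect_setequal(p, seq_len(n))
  }
})

test_that("permutation nulls are centered, reproducible and bounded below", {
  sim <- mk_sim_trials(M = 6, dur = 8, nch = 3, snr_db = 20, seed = 6)
  fitter <- function(tr) nested_cv(tr, "backward", sim$lagspec,
                                   lambda_grid = 100)$mean_score
  # independent-noise EEG: null centered at ~0
  noise_trials <- Map(function(f, e) list(features = f, eeg = e),
                      sim$feats, mk_noise_eeg(6, 8, nch = 3, seed = 11))
  nd0 <- permutation_null(noise_trials, fitter, n_permutations = 60,
                          seed = 3)
  expect_lt(abs(mean(nd0$scores)),
            2 * sd(nd0$scores) / sqrt(length(nd0$scores)) + 0.05)
  # strong coupling: observed beats every permutation
  nd <- permutation_null(sim$trials, fitter, n_permutations = 60,
                         seed = 3)
  expect_equal(nd$p_value, 1 / 61)
  nd2 <- permutation_null(sim$trials, fitter, n_permutations = 60,
                          seed = 3)
  expect_identical(nd$scores, nd2$scores)
  expect_error(permutation_null(sim$trials, fitter, n_permutations = 0),
               ">= 1")
  expect_error(permutation_null(sim$trials[1:4], fitter), "at least 5")
})

test_that("the cached nested-CV permutation null matches the generic path", {
  sim <- mk_sim_trials(M = 5, dur = 8, nch = 2, snr_db = 0, seed = 7)
  fitter <- function(tr) nested_cv(tr, "backward", sim$lagspec,
                                   lambda_grid = c(10, 1000))$mean_score
  slow <- permutation_null(sim$trials, fitter, n_permutations = 15,
                           seed = 9)
  fast <- nested_cv_permutation_null(sim$trials, "backward", sim$lagspec,
                                     lambda_grid = c(10, 1000),
                                     n_permutations = 15, seed = 9)
  expect_equal(fast$observed, slow$observed, tolerance = 1e-10)
  expect_equal(fast$scores, slow$scores, tolerance = 1e-10)
})

test_that("binomial chance thresholds match brute-force tail sums", {
  expect_equal(chance_threshold(840, 0.25, 0.05), 27.5)
  # large n: threshold approaches the chance probability
  expect_equal(chance_threshold(1e6, 0.25, 0.05), 25, tolerance = 0.01)
  # brute-force CDF oracle at n = 20
  n <- 20; p <- 0.5; alpha <- 0.05
  cdf <- cumsum(vapply(0:n, function(k) choose(n, k) * p^k *
                         (1 - p)^(n - k), numeric(1)))
  k_star <- min(which(cdf >= 1 - alpha)) - 1L  # 0-based count
  expect_equal(chance_threshold(n, p, alpha), 100 * k_star / n)
  # non-increasing in the number of trials
  grid <- c(20, 50, 100, 500, 2000, 10000)
  th <- vapply(grid, chance_threshold, numeric(1), p_chance = 0.25,
               alpha = 0.05)
  expect_true(all(diff(th) <= 1e-9))
  expect_error(chance_threshold(0, 0.25, 0.05))
  expect_error(chance_threshold(10, 1.2, 0.05))
})

test_that("bootstrap correlation CIs behave and reproduce", {
  set.seed(8)
  x <- rnorm(50); y <- x
  b <- bootstrap_correlation(x, y, n_boot = 300, seed = 1)
  expect_gte(b$ci[1], 0.99)
  b2 <- bootstrap_correlation(x, y, n_boot = 300, seed = 1)
  expect_identical(b$ci, b2$ci)
  expect_identical(b$boot_r, b2$boot_r)
  s <- bootstrap_correlation(rnorm(30), rnorm(30), n_boot = 100,
                             method = "spearman", seed = 2)
  expect_true(s$ci[1] <= s$r && s$r <= s$ci[2])
  expect_error(bootstrap_correlation(1:3, 1:3), "at least 5")
})

test_that("bootstrap CIs for independent data cover zero ~95% of the time", {
  set.seed(9)
  cover <- replicate(200, {
    x <- rnorm(100); y <- rnorm(100)
    ci <- bootstrap_correlation(x, y, n_boot = 200,
                                seed = sample.int(1e6, 1))$ci
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(cover), 0.9)
})

test_that("BH adjustment is monotone and bounded", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  q <- fdr_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
})
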