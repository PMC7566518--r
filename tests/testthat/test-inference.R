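test_that("sliding trial windows follow the floor count formula", {
  w1 <- sliding_trial_windows(100)
  expect_identical(nrow(w1), 1L)
  expect_identical(c(w1$start, w1$end), c(1L, 100L))

  w4 <- sliding_trial_windows(130)
  expect_identical(nrow(w4), 4L)
  expect_identical(w4$start, c(1L, 11L, 21L, 31L))
  expect_true(all(w4$end <= 130))

  w <- sliding_trial_windows(547, sliding_window_plan(window_size = 60,
                                                      step = 7))
  expect_identical(nrow(w), as.integer(floor((547 - 60) / 7) + 1))
  expect_true(all(w$end <= 547))
  expect_error(sliding_trial_windows(50), "at least 100")
})

test_that("accuracy series aggregates per window and aligns with windows", {
  expect_equal(accuracy_series(rep(1, 120)), rep(1, 3))
  expect_equal(accuracy_series(rep(c(0, 1), 60)), rep(0.5, 3))
  acc <- rbinom(240, 1, 0.7)
  expect_identical(length(accuracy_series(acc)),
                   nrow(sliding_trial_windows(240)))
  expect_error(accuracy_series(rep(1, 10)))
})

test_that("coupling series separates identical, coupled and null channels", {
  plan <- sliding_window_plan()
  sess <- simulate_task_session(task_session_params(n_trials = 200,
                                                    seed = 51))
  # a channel against itself: coherence 1 in every window
  cs_self <- coupling_series(sess$x, sess$x, plan)
  expect_lt(max(abs(cs_self$coupling - 1)), 1e-10)

  # independent noise: near zero
  wn <- simulate_task_session(task_session_params(
    n_trials = 200, coupling_profile = rep(0.02, 200), seed = 52))
  cs_null <- coupling_series(wn$x, wn$y, plan)
  expect_lt(mean(cs_null$coupling), 0.1)

  # rising drift: the series tracks the window-averaged profile
  cs <- coupling_series(sess$x, sess$y, plan)
  prof <- vapply(seq_len(nrow(cs)), function(i) {
    mean(sess$params$coupling_profile[cs$start[i]:cs$end[i]])
  }, numeric(1))
  expect_gt(cor(cs$coupling, prof, method = "spearman"), 0.8)
})

test_that("permutation thresholds are seeded and channel-symmetric", {
  wn <- simulate_white_noise(60, 64, 64, seed = 53)
  p1 <- permutation_max_threshold(wn$x, wn$y, NULL, c(8, 24),
                                  n_permutations = 300, seed = 7)
  p2 <- permutation_max_threshold(wn$x, wn$y, NULL, c(8, 24),
                                  n_permutations = 300, seed = 7)
  expect_identical(p1$threshold, p2$threshold)
  expect_identical(p1$null_max_samples, p2$null_max_samples)

  # permuting the other channel gives the same null distribution
  p3 <- permutation_max_threshold(wn$y, wn$x, NULL, c(8, 24),
                                  n_permutations = 1000, seed = 8)
  p4 <- permutation_max_threshold(wn$x, wn$y, NULL, c(8, 24),
                                  n_permutations = 1000, seed = 9)
  expect_equal(mean(p3$null_max_samples), mean(p4$null_max_samples),
               tolerance = 0.1)
  expect_error(permutation_max_threshold(wn$x, wn$y, NULL, c(8, 24),
                                         n_permutations = 50), "at least 100")
})

test_that("strong coupling clears the permutation threshold", {
  sess <- simulate_task_session(task_session_params(
    n_trials = 150, coupling_profile = rep(0.8, 150), seed = 54))
  plan <- sliding_window_plan()
  pn <- permutation_max_threshold(sess$x, sess$y, plan,
                                  n_permutations = 200, seed = 10)
  expect_gt(pn$observed_max, pn$threshold)
})

test_that("block bootstrap reproduces the plain Pearson r and flags y = x", {
  set.seed(55)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  r <- block_bootstrap_correlation(x, y, seed = 1)
  expect_equal(r$r, cor(x, y), tolerance = 1e-12)
  expect_true(r$ci_low <= r$r && r$r <= r$ci_high)

  rx <- block_bootstrap_correlation(x, x, seed = 2)
  expect_equal(rx$r, 1)
  expect_true(rx$significant)

  expect_error(block_bootstrap_correlation(rep(1, 20), rnorm(20)),
               "zero-variance")
  expect_error(block_bootstrap_correlation(rnorm(5), rnorm(5)), "at least 8")
})

test_that("block bootstrap CIs cover the null for autocorrelated pairs", {
  set.seed(56)
  cover <- vapply(1:500, function(i) {
    x <- as.numeric(stats::arima.sim(list(ar = 0.3), 60))
    y <- as.numeric(stats::arima.sim(list(ar = 0.3), 60))
    ci <- block_bootstrap_correlation(x, y, seed = i)
    ci$ci_low <= 0 && ci$ci_high >= 0
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("the dependent-correlation Z-test matches the published formula", {
  # independently coded reference for the two-dependent-correlations test
  # with one shared variable (back-transformed Fisher z difference)
  oracle <- function(r1, r2, r_between, n) {
    rbar2 <- (r1^2 + r2^2) / 2
    f <- (1 - r_between) / (2 * (1 - rbar2))
    if (f > 1) f <- 1
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- (atanh(r1) - atanh(r2)) *
      sqrt((n - 3) / (2 * (1 - r_between) * h))
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  got <- dependent_correlation_ztest(0.63, 0.53, 0.68, 85)
  want <- oracle(0.63, 0.53, 0.68, 85)
  expect_equal(got$z, want$z, tolerance = 1e-6)
  expect_equal(got$p_two_tailed, want$p, tolerance = 1e-6)

  eq <- dependent_correlation_ztest(0.4, 0.4, 0.2, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_tailed, 1)

  ab <- dependent_correlation_ztest(0.6, 0.3, 0.5, 40)
  ba <- dependent_correlation_ztest(0.3, 0.6, 0.5, 40)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_two_tailed, ba$p_two_tailed)

  expect_error(dependent_correlation_ztest(1, 0.5, 0.2, 30), "strictly")
  expect_error(dependent_correlation_ztest(0.5, 0.4, 0.2, 3), "at least 4")
})

test_that("the end-to-end pipeline recovers a built-in coupling link", {
  sess <- simulate_task_session(task_session_params(seed = 57))
  res <- task_coupling_analysis(sess$x, sess$y, sess$accuracy,
                                n_permutations = 200, seed = 58)
  expect_gt(res$correlation$r, 0)
  expect_true(res$correlation$significant)
  expect_identical(nrow(res$windows),
                   nrow(sliding_trial_windows(400)))
  expect_true(all(c("coupling", "accuracy", "passed_threshold",
                    "coupling_used") %in% names(res$windows)))
  # sub-threshold zeroing leaves passing windows untouched
  keep <- res$windows$passed_threshold
  expect_identical(res$windows$coupling_used[keep],
                   res$windows$coupling[keep])
})
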