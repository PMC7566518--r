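test_that("analytic kurtosis matches the moment formulas and Monte Carlo", {
  expect_equal(analytic_kurtosis("rayleigh"), 3)
  expect_equal(analytic_kurtosis("uniform"), 2.7)
  expect_error(analytic_kurtosis("cauchy"))

  # marginal at a fixed time point across many paths
  sr <- simulate_random_sinusoids(
    sinusoid_model_params(n_paths = 1e5, n_samples = 8, fs = 64, f0 = 8,
                          seed = 11))
  expect_lt(abs(sample_kurtosis(sr$x$data[, 3]) - 3), 0.05)
  su <- simulate_random_sinusoids(
    sinusoid_model_params(n_paths = 1e5, n_samples = 8, fs = 64, f0 = 8,
                          amplitude_family = "uniform", seed = 12))
  expect_lt(abs(sample_kurtosis(su$x$data[, 3]) - 2.7), 0.05)
})

test_that("simulated paths are seed-reproducible and respect the noise limit", {
  a <- gp_paths(n_paths = 20, seed = 5)
  b <- gp_paths(n_paths = 20, seed = 5)
  c <- gp_paths(n_paths = 20, seed = 6)
  expect_identical(a$x$data, b$x$data)
  expect_identical(a$y$data, b$y$data)
  expect_false(identical(a$x$data, c$x$data))

  # sigma_b = 0: W vanishes and Y equals X elementwise
  s0 <- gp_paths(n_paths = 20, sigma_b = 0, seed = 7)
  expect_identical(s0$x$data, s0$y$data)
})

test_that("model parameter validation catches bad inputs", {
  expect_error(sinusoid_model_params(f0 = 64, fs = 128), "Nyquist")
  expect_error(sinusoid_model_params(n_samples = 4), "n_samples")
  expect_error(sinusoid_model_params(amplitude_family = "gamma"))
  expect_error(simulate_random_sinusoids(list(f0 = 8)))
})

test_that("true MIF of the Gaussian model and its inverse are consistent", {
  expect_equal(true_mif_gp(1), log(2))
  expect_equal(true_mif_gp(1 / sqrt(exp(1) - 1)), 1)
  expect_lt(true_mif_gp(1e6), 1e-11)          # no-signal limit
  # strictly decreasing in sigma_b
  grid <- true_mif_gp(seq(0.2, 5, by = 0.2))
  expect_true(all(diff(grid) < 0))

  expect_equal(sigma_b_for_true_mif(log(2)), 1)
  expect_equal(sigma_b_for_true_mif(1), 1 / sqrt(exp(1) - 1),
               tolerance = 1e-12)
  expect_equal(sigma_b_for_true_mif(1), 0.7629, tolerance = 1e-4)
  for (mi in c(0.2, 0.8, 1.4)) {
    expect_equal(true_mif_gp(sigma_b_for_true_mif(mi)), mi,
                 tolerance = 1e-12)
  }
  expect_error(sigma_b_for_true_mif(0))
  expect_error(true_mif_gp(-1))
})

test_that("task sessions link accuracy to coupling as configured", {
  # null link: success probability flat regardless of the coupling drift
  p0 <- task_session_params(n_trials = 150, accuracy_link = 0, seed = 1)
  s0 <- simulate_task_session(p0)
  expect_true(all(s0$p_correct == s0$p_correct[1]))

  # constant profile: zero-variance regressor
  pc <- task_session_params(n_trials = 150,
                            coupling_profile = rep(0.5, 150), seed = 2)
  sc <- simulate_task_session(pc)
  expect_equal(sd(sc$p_correct), 0)

  # positive link: generating success probability increases with coupling
  pp <- task_session_params(n_trials = 150, accuracy_link = 5, seed = 3)
  sp <- simulate_task_session(pp)
  expect_true(cor(sp$p_correct, pp$coupling_profile) > 0.99)
  expect_true(all(sp$accuracy %in% c(0, 1)))
  expect_identical(dim(sp$x$data),
                   c(150L, as.integer(round(3.6 * pp$fs))))

  expect_error(task_session_params(n_trials = 50), "at least 120")
  expect_error(task_session_params(band = c(4, 100)), "band")
})

test_that("sessions export to delimited text and read back", {
  dir <- withr::local_tempdir()
  s <- simulate_task_session(task_session_params(n_trials = 120, seed = 4))
  paths <- write_session(s, dir)
  x2 <- read_trial_matrix(paths["x"])
  expect_equal(x2$data, s$x$data)
  expect_equal(x2$fs, s$x$fs)
  expect_equal(as.numeric(readLines(paths["accuracy"])), s$accuracy)
})
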