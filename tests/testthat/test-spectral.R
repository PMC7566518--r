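test_that("window conditioning zeroes row means and is idempotent", {
  w <- trial_window_set(matrix(rnorm(200, mean = 3), 10, 20), fs = 20)
  cw <- condition_windows(w)
  expect_lt(max(abs(rowMeans(cw$data))), 1e-12)
  expect_equal(condition_windows(cw)$data, cw$data, tolerance = 1e-12)
  # constant rows become zero rows
  k <- trial_window_set(matrix(5, 3, 8), fs = 8)
  expect_true(all(condition_windows(k)$data == 0))
})

test_that("increments obey the discrete Fourier identity for a cosine", {
  N <- 64; fs <- 64; f0 <- 8; a <- 1.7
  w <- trial_window_set(
    matrix(a * cos(2 * pi * f0 * (0:(N - 1)) / fs), 1, N, byrow = TRUE), fs)
  inc <- fourier_increment_samples(w, rect_taper(N), f0)
  expect_equal(Re(inc$values[1, 1]), a / 2, tolerance = 1e-10)
  expect_lt(abs(Im(inc$values[1, 1])), 1e-10)

  # zero input gives zero increments
  z <- trial_window_set(matrix(0, 2, N), fs)
  expect_true(all(fourier_increment_samples(z, rect_taper(N), f0)$values == 0))

  # off-grid frequencies error unless snapped
  expect_error(fourier_increment_samples(w, rect_taper(N), 8.3), "grid")
  snapped <- fourier_increment_samples(w, rect_taper(N), 8.3,
                                       nearest_bin = TRUE)
  expect_equal(snapped$frequency, 8)
})

test_that("random-phase trials give isotropic increment samples", {
  set.seed(3)
  N <- 64; fs <- 64; f0 <- 8; n <- 1e4
  ph <- runif(n, 0, 2 * pi)
  w <- trial_window_set(2 * cos(outer(ph, 2 * pi * f0 * (0:(N - 1)) / fs,
                                      `+`)), fs)
  v <- fourier_increment_samples(w, rect_taper(N), f0)$values
  expect_lt(abs(mean(Re(v))), 0.03)
  expect_lt(abs(mean(Im(v))), 0.03)
})

test_that("coherence is 1 for a channel with itself and ~0 for noise", {
  s <- gp_paths(n_paths = 100, seed = 21)
  cs <- estimate_coherence(s$x, s$x)
  powered <- !is.na(cs$coherence)
  expect_true(any(powered))
  expect_lt(max(abs(cs$coherence[powered] - 1)), 1e-10)

  wn <- simulate_white_noise(2000, 64, 64, seed = 22)
  tp <- generate_dpss(64, nw = 3, n_tapers = 5)
  cw <- estimate_coherence(wn$x, wn$y, tp)
  expect_lt(max(cw$coherence, na.rm = TRUE), 0.01)
})

test_that("coherence is scale invariant and bounded in [0, 1]", {
  s <- gp_paths(n_paths = 80, seed = 23)
  c1 <- estimate_coherence(s$x, s$y)
  xs <- trial_window_set(17.3 * s$x$data, s$x$fs)
  ys <- trial_window_set(0.004 * s$y$data, s$y$fs)
  c2 <- estimate_coherence(xs, ys)
  expect_equal(c1$coherence, c2$coherence, tolerance = 1e-10)

  wn <- simulate_white_noise(50, 32, 32, seed = 24)
  cc <- estimate_coherence(wn$x, wn$y)$coherence
  expect_true(all(cc >= 0 & cc <= 1, na.rm = TRUE))
})

test_that("pooled and per-taper-averaged spectral routes agree exactly", {
  s <- gp_paths(n_paths = 60, seed = 25)
  tp <- generate_dpss(128, 2, 3)
  cs <- multitaper_spectra(s$x, s$y, tp)
  # recompute by averaging per-taper cross-spectra, then across tapers
  xw <- condition_windows(s$x); yw <- condition_windows(s$y)
  f0 <- 8
  per_taper <- sapply(1:3, function(k) {
    ix <- fourier_increment_samples(xw, single_taper(tp, k), f0)$values
    iy <- fourier_increment_samples(yw, single_taper(tp, k), f0)$values
    c(sxy = mean(ix * Conj(iy)), sx = mean(Mod(ix)^2), sy = mean(Mod(iy)^2))
  })
  coh_pre_route <- Mod(mean(per_taper[1, ]))^2 /
    (Re(mean(per_taper[2, ])) * Re(mean(per_taper[3, ])))
  expect_equal(cs$coherence[cs$frequencies == f0], coh_pre_route,
               tolerance = 1e-10)
})

test_that("white-noise increments at distinct bins are uncorrelated", {
  wn <- simulate_white_noise(1e4, 64, 64, seed = 26)
  tp <- rect_taper(64)
  v8 <- fourier_increment_samples(wn$x, tp, 8)$values
  v16 <- fourier_increment_samples(wn$x, tp, 16)$values
  expect_lt(abs(cor(Re(v8), Re(v16))), 0.05)
  expect_lt(abs(cor(Im(v8), Im(v16))), 0.05)
})

test_that("Gaussian-model coherence at f0 matches the closed form", {
  # C(f0) = 1 / (1 + sigma_b^2) = 0.5 at sigma_b = 1
  s <- gp_paths(n_paths = 1e4, seed = 27)
  cs <- estimate_coherence(s$x, s$y, frequencies = 8)
  expect_equal(cs$coherence, 0.5, tolerance = 0.02)
})

test_that("spectral input validation catches mismatches", {
  s <- gp_paths(n_paths = 10, seed = 28)
  short <- trial_window_set(s$y$data[1:5, ], s$y$fs)
  expect_error(multitaper_spectra(s$x, short), "trial counts")
  refs <- trial_window_set(s$y$data, 100)
  expect_error(multitaper_spectra(s$x, refs), "sampling rate")
})
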