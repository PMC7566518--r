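#' FFT bin frequencies of a window
#'
#' The non-negative frequency grid `fs * m / n, m = 0 .. floor(n/2)` of an
#' n-sample window at sampling rate fs.
#'
#' @param n_samples window length.
#' @param fs sampling rate (Hz).
#' @return Numeric vector of frequencies in Hz.
#' @export
fft_bin_freqs <- function(n_samples, fs) {
  fs * (0:(n_samples %/% 2)) / n_samples
}

# Validate that frequencies sit on the FFT grid; optionally snap to the
# nearest bin instead of erroring.
.on_grid <- function(freqs, n_samples, fs, nearest_bin = FALSE) {
  m <- freqs * n_samples / fs
  off <- abs(m - round(m))
  if (any(off > 1e-6)) {
    if (nearest_bin) {
      freqs <- fs * round(m) / n_samples
    } else {
      bad <- freqs[off > 1e-6][1]
      stop(sprintf(paste0("frequency %g Hz is not on the FFT bin grid ",
                          "fs*m/N (resolution %g Hz); pass nearest_bin = ",
                          "TRUE to snap"), bad, fs / n_samples))
    }
  }
  if (any(freqs < 0) || any(freqs > fs / 2)) {
    stop("frequencies must lie in [0, fs/2]")
  }
  freqs
}

# Complex increment tensor [trial, taper, frequency]:
#   value = (1/N) * sum_n taper[n] * w[trial, n] * exp(-j 2 pi f n / fs)
.increment_tensor <- function(w, tapers, freqs) {
  N <- ncol(w$data)
  K <- nrow(tapers$tapers)
  E <- exp(-2i * pi * outer(0:(N - 1), freqs) / w$fs)  # N x F
  out <- array(0i, dim = c(nrow(w$data), K, length(freqs)))
  for (k in seq_len(K)) {
    out[, k, ] <- w$data %*% (tapers$tapers[k, ] * E) / N
  }
  out
}

#' Fourier increment samples at one frequency
#'
#' Samples of the complex Fourier increment of a process at frequency f: each
#' trial, multiplied point-wise by each taper and Fourier-transformed at f,
#' contributes one complex sample. These (trial x taper) samples are the raw
#' material of both the multitaper spectra and the MIF estimators; each sample
#' is treated downstream as the 2-vector of its real and imaginary parts.
#'
#' The 1/N normalization is fixed for reproducibility; coherence is invariant
#' to it and MIF is invariant to any invertible linear map of the samples.
#'
#' @param w a [trial_window_set()].
#' @param tapers a [taper_set()] whose length matches the window.
#' @param frequency frequency in Hz; must sit on the FFT bin grid
#'   `fs * m / N` unless `nearest_bin = TRUE`.
#' @param nearest_bin snap an off-grid frequency to the nearest bin instead of
#'   erroring.
#' @return An object of class `"increment_samples"`: list with `frequency` and
#'   `values`, a trials x tapers complex matrix.
#' @export
fourier_increment_samples <- function(w, tapers, frequency,
                                      nearest_bin = FALSE) {
  .check_tws(w)
  .check_tapers(tapers, ncol(w$data))
  frequency <- .on_grid(frequency, ncol(w$data), w$fs, nearest_bin)
  vals <- .increment_tensor(w, tapers, frequency)[, , 1, drop = TRUE]
  vals <- matrix(vals, nrow = nrow(w$data))
  structure(list(frequency = frequency, values = vals),
            class = "increment_samples")
}

#' @export
print.increment_samples <- function(x, ...) {
  cat(sprintf("<increment_samples> f = %g Hz, %d trials x %d tapers\n",
              x$frequency, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Multitaper power spectra, cross-spectrum and coherence
#'
#' Estimates the power spectral densities of two channels, their
#' cross-spectral density, and the magnitude-squared coherence
#' \deqn{\hat C_{XY}(f) = |\hat S_{XY}(f)|^2 / (\hat S_X(f) \hat S_Y(f))}
#' by averaging single-taper single-trial spectral estimates across all
#' (trial, taper) pairs. Pooling all pairs and averaging per-taper estimates
#' give the identical result (equal-sized groups), so the "naive" and
#' taper-wise averaging routes to coherence coincide; the complex
#' pre-averaging used by the MIF `pre` strategy is not applied to spectra.
#'
#' Windows are demeaned per trial by default to keep DC leakage out of
#' low-frequency bins.
#'
#' @param x,y [trial_window_set()]s with equal trial counts and sampling
#'   rates.
#' @param tapers a [taper_set()]; default DPSS with `nw = 2`, 3 tapers.
#' @param frequencies frequencies in Hz (on the FFT grid); default the full
#'   grid of [fft_bin_freqs()].
#' @param demean subtract each trial's mean first (default TRUE).
#' @param nearest_bin snap off-grid frequencies to the nearest bin.
#' @return An object of class `"coherence_spectrum"`: list with
#'   `frequencies`, `sx`, `sy` (real PSD estimates), `sxy` (complex),
#'   `coherence` in `[0, 1]` (NA at bins where either channel has zero
#'   power), and metadata `n_trials`, `n_tapers`, `fs`.
#' @examples
#' s <- simulate_random_sinusoids(sinusoid_model_params(n_paths = 50, seed = 1))
#' cs <- estimate_coherence(s$x, s$y)
#' cs$coherence[cs$frequencies == 8]
#' @export
multitaper_spectra <- function(x, y, tapers = NULL, frequencies = NULL,
                               demean = TRUE, nearest_bin = FALSE) {
  .check_tws(x); .check_tws(y)
  if (nrow(x$data) != nrow(y$data)) stop("x and y must have equal trial counts")
  if (ncol(x$data) != ncol(y$data)) stop("x and y must have equal window lengths")
  if (x$fs != y$fs) stop("x and y must share a sampling rate")
  N <- ncol(x$data)
  if (is.null(tapers)) tapers <- generate_dpss(N)
  .check_tapers(tapers, N)
  if (is.null(frequencies)) frequencies <- fft_bin_freqs(N, x$fs)
  frequencies <- .on_grid(frequencies, N, x$fs, nearest_bin)
  if (demean) {
    x <- condition_windows(x)
    y <- condition_windows(y)
  }
  IX <- .increment_tensor(x, tapers, frequencies)
  IY <- .increment_tensor(y, tapers, frequencies)
  nf <- length(frequencies)
  sx <- sy <- numeric(nf)
  sxy <- complex(nf)
  for (f in seq_len(nf)) {
    sx[f] <- mean(Mod(IX[, , f])^2)
    sy[f] <- mean(Mod(IY[, , f])^2)
    sxy[f] <- mean(IX[, , f] * Conj(IY[, , f]))
  }
  coh <- ifelse(sx > 0 & sy > 0, pmin(Mod(sxy)^2 / (sx * sy), 1), NA_real_)
  structure(list(frequencies = frequencies, sx = sx, sy = sy, sxy = sxy,
                 coherence = coh, n_trials = nrow(x$data),
                 n_tapers = nrow(tapers$tapers), fs = x$fs),
            class = "coherence_spectrum")
}

#' @rdname multitaper_spectra
#' @export
estimate_coherence <- function(x, y, tapers = NULL, frequencies = NULL,
                               demean = TRUE, nearest_bin = FALSE) {
  multitaper_spectra(x, y, tapers, frequencies, demean, nearest_bin)
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<coherence_spectrum> %d bins, %d trials x %d tapers ",
                     "@ %g Hz\n"),
              length(x$frequencies), x$n_trials, x$n_tapers, x$fs))
  invisible(x)
}

#' @export
as.data.frame.coherence_spectrum <- function(x, ...) {
  data.frame(frequency = x$frequencies, sx = x$sx, sy = x$sy,
             re_sxy = Re(x$sxy), im_sxy = Im(x$sxy), coherence = x$coherence)
}
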