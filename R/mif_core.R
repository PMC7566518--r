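#' Coherence to MIF transform for Gaussian processes
#'
#' For linearly related Gaussian processes, same-frequency mutual information
#' in frequency and coherence are linked by
#' \deqn{MI(f, f) = -\log(1 - C_{XY}(f))} nats. Applying this transform to
#' estimated coherence of a non-Gaussian pair underestimates the MIF, which is
#' exactly the information gap the MIF estimator is built to expose.
#'
#' @param c coherence value(s) in `[0, 1]`. `c = 1` returns `Inf` with a
#'   warning; values outside `[0, 1]` are an error.
#' @return MIF in nats.
#' @examples
#' coherence_to_mif(0.5)  # log(2)
#' @export
coherence_to_mif <- function(c) {
  if (any(!is.finite(c)) || any(c < 0) || any(c > 1)) {
    stop("coherence must lie in [0, 1]")
  }
  if (any(c == 1)) warning("coherence of 1 maps to infinite MIF")
  -log(1 - c)
}

#' MIF to coherence transform
#'
#' Inverse of [coherence_to_mif()]: the coherence a Gaussian-process pair
#' would need to carry `mi` nats at a single frequency,
#' \eqn{C = 1 - e^{-mi}}. Monotone increasing and bounded below 1.
#'
#' @param mi MIF in nats (non-negative).
#' @return Coherence in `[0, 1)`.
#' @export
mif_to_coherence <- function(mi) {
  if (any(mi < 0)) stop("mi must be non-negative")
  -expm1(-mi)
}

# Resolve the neighbour count for a strategy given the effective sample count
# fed to the estimator.
.resolve_k <- function(cfg, strategy, n_eff) {
  k <- switch(cfg$k_rule,
              fixed = cfg$k_fixed,
              half_samples = max(1L, floor(n_eff / 2)),
              strategy_default = if (strategy == "pre") 3L
                                 else max(1L, floor(n_eff / 2)))
  if (k >= n_eff) stop(sprintf("k = %d requires more than %d samples", k, n_eff))
  as.integer(k)
}

.complex_to_mat <- function(z) cbind(Re(z), Im(z))

.mi_pair <- function(xs, ys, cfg, k) {
  switch(cfg$method,
         knn = knn_mi(xs, ys, k, clip_negative = cfg$clip_negative,
                      jitter_scale = cfg$jitter_scale),
         hist_fixed = histogram_mi_fixed(xs, ys, cfg$n_bins),
         hist_adaptive = histogram_mi_adaptive(xs, ys, cfg$n_bins),
         stop(sprintf("method '%s' is not a sample-based estimator",
                      cfg$method)))
}

# MIF from complex increment matrices (trials x tapers), one per channel.
.mif_from_increments <- function(IX, IY, cfg, strategy) {
  n <- nrow(IX)
  K <- ncol(IX)
  if (strategy == "naive") {
    k <- .resolve_k(cfg, strategy, n * K)
    .mi_pair(.complex_to_mat(as.vector(IX)), .complex_to_mat(as.vector(IY)),
             cfg, k)
  } else if (strategy == "pre") {
    k <- .resolve_k(cfg, strategy, n)
    .mi_pair(.complex_to_mat(rowMeans(IX)), .complex_to_mat(rowMeans(IY)),
             cfg, k)
  } else { # post: average per-taper estimates
    k <- .resolve_k(cfg, strategy, n)
    mean(vapply(seq_len(K), function(j) {
      .mi_pair(.complex_to_mat(IX[, j]), .complex_to_mat(IY[, j]), cfg, k)
    }, numeric(1)))
  }
}

#' MIF at one frequency pair
#'
#' Estimates the mutual information between the Fourier increments of channel
#' x at `f_i` and channel y at `f_j`. Increment samples are computed per
#' (trial, taper) and combined across tapers by one of three strategies:
#'
#' * `"naive"`: all trial x taper complex samples pooled into one estimate;
#' * `"pre"`: samples averaged across tapers in the complex plane per trial,
#'   then one estimate from `n_trials` samples (bias-oriented; default k = 3);
#' * `"post"`: one estimate per taper, estimates averaged (variance-oriented;
#'   default k = floor(n_trials / 2)).
#'
#' Each complex increment enters the estimator as its `[real, imaginary]`
#' 2-vector, so MI is between two 2-dimensional variables.
#'
#' @param x,y [trial_window_set()]s with equal trial counts and rates.
#' @param f_i,f_j frequencies in Hz on the FFT bin grid.
#' @param tapers a [taper_set()]; default DPSS `nw = 2`, 3 tapers.
#' @param cfg an [estimator_config()].
#' @param strategy `"post"`, `"pre"` or `"naive"`.
#' @param demean subtract per-trial means before tapering.
#' @param nearest_bin snap off-grid frequencies to the nearest bin.
#' @return MIF estimate in nats.
#' @export
estimate_mif_at <- function(x, y, f_i, f_j, tapers = NULL,
                            cfg = estimator_config(),
                            strategy = c("post", "pre", "naive"),
                            demean = TRUE, nearest_bin = FALSE) {
  strategy <- match.arg(strategy)
  .check_tws(x); .check_tws(y)
  if (nrow(x$data) != nrow(y$data)) stop("x and y must have equal trial counts")
  if (x$fs != y$fs) stop("x and y must share a sampling rate")
  if (is.null(tapers)) tapers <- generate_dpss(ncol(x$data))
  if (demean) {
    x <- condition_windows(x)
    y <- condition_windows(y)
  }
  IX <- fourier_increment_samples(x, tapers, f_i, nearest_bin)$values
  IY <- fourier_increment_samples(y, tapers, f_j, nearest_bin)$values
  .mif_from_increments(IX, IY, cfg, strategy)
}

#' MIF matrix over frequency pairs
#'
#' Computes [estimate_mif_at()] for every pair `(f_i, f_j)` of the supplied
#' grids. Unlike coherence, MIF is defined for cross-frequency pairs; for the
#' simulation models only the diagonal carries known ground truth.
#'
#' @param x,y [trial_window_set()]s.
#' @param freqs_x,freqs_y frequency grids in Hz (on FFT bins).
#' @inheritParams estimate_mif_at
#' @return An object of class `"mif_matrix"`: list with `freqs_x`, `freqs_y`,
#'   `values` (MI in nats, rows indexed by `freqs_x`), `strategy`, `cfg`,
#'   `n_trials`, `n_tapers`.
#' @export
mif_matrix <- function(x, y, freqs_x, freqs_y = freqs_x, tapers = NULL,
                       cfg = estimator_config(),
                       strategy = c("post", "pre", "naive"),
                       demean = TRUE, nearest_bin = FALSE) {
  strategy <- match.arg(strategy)
  .check_tws(x); .check_tws(y)
  if (nrow(x$data) != nrow(y$data)) stop("x and y must have equal trial counts")
  if (x$fs != y$fs) stop("x and y must share a sampling rate")
  N <- ncol(x$data)
  if (is.null(tapers)) tapers <- generate_dpss(N)
  if (demean) {
    x <- condition_windows(x)
    y <- condition_windows(y)
  }
  freqs_x <- .on_grid(freqs_x, N, x$fs, nearest_bin)
  freqs_y <- .on_grid(freqs_y, N, y$fs, nearest_bin)
  IX <- .increment_tensor(x, tapers, freqs_x)
  IY <- .increment_tensor(y, tapers, freqs_y)
  vals <- matrix(NA_real_, length(freqs_x), length(freqs_y))
  for (i in seq_along(freqs_x)) {
    IXi <- matrix(IX[, , i], nrow = nrow(x$data))
    for (j in seq_along(freqs_y)) {
      vals[i, j] <- .mif_from_increments(
        IXi, matrix(IY[, , j], nrow = nrow(y$data)), cfg, strategy)
    }
  }
  structure(list(freqs_x = freqs_x, freqs_y = freqs_y, values = vals,
                 strategy = strategy, cfg = cfg, n_trials = nrow(x$data),
                 n_tapers = nrow(tapers$tapers)),
            class = "mif_matrix")
}

#' @export
print.mif_matrix <- function(x, ...) {
  cat(sprintf(paste0("<mif_matrix> %d x %d frequency pairs, strategy '%s', ",
                     "%d trials x %d tapers (nats)\n"),
              length(x$freqs_x), length(x$freqs_y), x$strategy, x$n_trials,
              x$n_tapers))
  invisible(x)
}

#' @export
as.data.frame.mif_matrix <- function(x, ...) {
  data.frame(f_x = rep(x$freqs_x, times = length(x$freqs_y)),
             f_y = rep(x$freqs_y, each = length(x$freqs_x)),
             mi_nats = as.vector(x$values),
             strategy = x$strategy, estimator = x$cfg$method,
             n_trials = x$n_trials, n_tapers = x$n_tapers)
}

#' Band-average coupling
#'
#' Averages a coupling measure over the frequency bins whose centres fall in
#' `[band[1], band[2]]` (inclusive). For a coherence spectrum the per-bin
#' coherence is averaged; for an MIF matrix only the same-frequency (diagonal)
#' values are used, so the summary is commensurate with coherence.
#'
#' @param x a `coherence_spectrum`, `mif_matrix`, or numeric vector of per-bin
#'   values (then `freqs` is required).
#' @param band `(low, high)` in Hz.
#' @param freqs bin centre frequencies for the default method.
#' @param mode aggregation mode; only `"mean"` is defined.
#' @return A scalar band coupling value.
#' @export
band_coupling <- function(x, band, freqs = NULL, mode = "mean") {
  mode <- match.arg(mode, "mean")
  UseMethod("band_coupling")
}

#' @export
band_coupling.coherence_spectrum <- function(x, band, freqs = NULL,
                                             mode = "mean") {
  band_coupling.default(x$coherence, band, x$frequencies)
}

#' @export
band_coupling.mif_matrix <- function(x, band, freqs = NULL, mode = "mean") {
  common <- intersect(x$freqs_x, x$freqs_y)
  idx <- common[common >= band[1] & common <= band[2]]
  if (length(idx) == 0) stop("no frequency bins inside the band")
  vals <- vapply(idx, function(f) {
    x$values[match(f, x$freqs_x), match(f, x$freqs_y)]
  }, numeric(1))
  mean(vals)
}

#' @export
band_coupling.default <- function(x, band, freqs = NULL, mode = "mean") {
  if (is.null(freqs)) stop("freqs required for a plain numeric input")
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(x[sel])
}
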