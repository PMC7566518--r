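#' Sliding trial-window plan
#'
#' Layout of the sliding-window coupling analysis: overlapping windows of
#' `window_size` trials advanced by `step` trials, with coupling estimated in
#' several short sub-windows of each trial and averaged. The defaults mirror a
#' delayed match-to-sample session: 100-trial windows slid by 10, and three
#' 300 ms sub-windows starting at 1.6, 1.65 and 1.7 s after trial onset
#' (late second-stimulus presentation into the decision period).
#'
#' @param window_size trials per window.
#' @param step trial shift between consecutive windows.
#' @param sub_window_starts sub-window start times (s, relative to trial
#'   reference).
#' @param sub_window_length sub-window length (s).
#' @return An object of class `"sliding_window_plan"`.
#' @export
sliding_window_plan <- function(window_size = 100, step = 10,
                                sub_window_starts = c(1.6, 1.65, 1.7),
                                sub_window_length = 0.3) {
  if (window_size < 2) stop("window_size must be at least 2")
  if (step < 1) stop("step must be at least 1")
  if (sub_window_length <= 0) stop("sub_window_length must be positive")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 sub_window_starts = sub_window_starts,
                 sub_window_length = sub_window_length),
            class = "sliding_window_plan")
}

#' Sliding trial-window index ranges
#'
#' The trial index ranges `[1, w], [1 + s, w + s], ...` covered by a plan;
#' the count is `floor((n_trials - window_size) / step) + 1`.
#'
#' @param n_trials total trials available.
#' @param plan a [sliding_window_plan()].
#' @return A data frame with columns `window`, `start`, `end` (1-based,
#'   inclusive).
#' @export
sliding_trial_windows <- function(n_trials, plan = sliding_window_plan()) {
  if (n_trials < plan$window_size) {
    stop(sprintf("need at least %d trials, got %d", plan$window_size,
                 n_trials))
  }
  starts <- as.integer(seq(1L, n_trials - plan$window_size + 1L,
                           by = plan$step))
  data.frame(window = seq_along(starts), start = starts,
             end = starts + plan$window_size - 1L)
}

#' Per-window task accuracy
#'
#' Fraction of correct trials in each sliding window.
#'
#' @param accuracy per-trial 0/1 vector.
#' @param plan a [sliding_window_plan()].
#' @return Numeric vector, one mean accuracy per window.
#' @export
accuracy_series <- function(accuracy, plan = sliding_window_plan()) {
  w <- sliding_trial_windows(length(accuracy), plan)
  vapply(seq_len(nrow(w)), function(i) mean(accuracy[w$start[i]:w$end[i]]),
         numeric(1))
}

# Sub-window descriptors for a plan (or the whole window when plan is NULL).
.sub_specs <- function(x, plan) {
  if (is.null(plan)) {
    return(list(list(start = x$t0, len = ncol(x$data) / x$fs)))
  }
  lapply(plan$sub_window_starts, function(s) {
    list(start = s, len = plan$sub_window_length)
  })
}

# Precompute, for each sub-window, the band-bin increment structures needed
# by the coupling and permutation statistics.
.band_increments <- function(x, y, plan, band, tapers = NULL, demean = TRUE) {
  specs <- .sub_specs(x, plan)
  lapply(specs, function(sp) {
    xs <- subwindow(x, sp$start, sp$len)
    ys <- subwindow(y, sp$start, sp$len)
    N <- ncol(xs$data)
    tp <- tapers %||% generate_dpss(N)
    .check_tapers(tp, N)
    freqs <- fft_bin_freqs(N, x$fs)
    bins <- freqs[freqs >= band[1] & freqs <= band[2]]
    if (length(bins) == 0) {
      stop("band contains no frequency bins at this sub-window length")
    }
    if (demean) {
      xs <- condition_windows(xs)
      ys <- condition_windows(ys)
    }
    IX <- .increment_tensor(xs, tp, bins)
    IY <- .increment_tensor(ys, tp, bins)
    n <- dim(IX)[1]; K <- dim(IX)[2]; B <- dim(IX)[3]
    list(IX = IX, IY = IY, Mx = matrix(IX, n, K * B),
         MyC = Conj(matrix(IY, n, K * B)), K = K, B = B, bins = bins)
  })
}

# Per-bin coherence for a trial subset (and optional permutation of the y
# channel), averaged over sub-windows.
.bin_coherence <- function(pre, idx = NULL, perm = NULL) {
  cohs <- vapply(pre, function(p) {
    Mx <- if (is.null(idx)) p$Mx else p$Mx[idx, , drop = FALSE]
    My <- if (is.null(idx)) p$MyC else p$MyC[idx, , drop = FALSE]
    if (!is.null(perm)) My <- My[perm, , drop = FALSE]
    cross <- colMeans(Mx * My)
    sxy <- colMeans(matrix(cross, p$K, p$B))
    sx <- colMeans(matrix(colMeans(Mod(Mx)^2), p$K, p$B))
    sy <- colMeans(matrix(colMeans(Mod(My)^2), p$K, p$B))
    pmin(Mod(sxy)^2 / (sx * sy), 1)
  }, numeric(pre[[1]]$B))
  rowMeans(matrix(cohs, nrow = pre[[1]]$B))
}

# Per-bin post-strategy MIF for a trial subset, averaged over sub-windows.
.bin_mif_post <- function(pre, cfg, idx = NULL, perm = NULL) {
  vals <- vapply(pre, function(p) {
    vapply(seq_len(p$B), function(b) {
      IX <- matrix(p$IX[, , b], nrow = dim(p$IX)[1])
      IY <- matrix(p$IY[, , b], nrow = dim(p$IY)[1])
      if (!is.null(idx)) {
        IX <- IX[idx, , drop = FALSE]
        IY <- IY[idx, , drop = FALSE]
      }
      if (!is.null(perm)) IY <- IY[perm, , drop = FALSE]
      .mif_from_increments(IX, IY, cfg, "post")
    }, numeric(1))
  }, numeric(pre[[1]]$B))
  rowMeans(matrix(vals, nrow = pre[[1]]$B))
}

.bin_coupling <- function(pre, method, cfg, idx = NULL, perm = NULL) {
  if (method == "coherence") .bin_coherence(pre, idx, perm)
  else .bin_mif_post(pre, cfg, idx, perm)
}

#' Sliding-window coupling series
#'
#' For each sliding trial window, estimates band coupling (mean over band
#' bins) in each sub-window of the plan and averages the sub-window estimates
#' into one scalar per window. `method = "coherence"` uses multitaper
#' coherence; `method = "mif_post"` uses the post-strategy k-NN MIF at the
#' diagonal band bins. The per-window maximum across band bins is also
#' returned, as that is the statistic compared against the permutation
#' max-statistic threshold.
#'
#' @param x,y [trial_window_set()]s holding whole trials.
#' @param plan a [sliding_window_plan()].
#' @param band `(low, high)` in Hz.
#' @param method `"coherence"` or `"mif_post"`.
#' @param cfg [estimator_config()] for the MIF method.
#' @param tapers optional [taper_set()] matching the sub-window length;
#'   default DPSS `nw = 2`, 3 tapers.
#' @param demean subtract per-trial sub-window means.
#' @return A data frame with `window`, `start`, `end`, `coupling`,
#'   `max_bin_coupling`; the band bin frequencies are attached as attribute
#'   `"bins"`.
#' @export
coupling_series <- function(x, y, plan = sliding_window_plan(),
                            band = c(4, 8),
                            method = c("coherence", "mif_post"),
                            cfg = estimator_config(), tapers = NULL,
                            demean = TRUE) {
  method <- match.arg(method)
  .check_tws(x); .check_tws(y)
  if (nrow(x$data) != nrow(y$data)) stop("x and y must have equal trial counts")
  w <- sliding_trial_windows(nrow(x$data), plan)
  pre <- .band_increments(x, y, plan, band, tapers, demean)
  coupling <- maxbin <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    bc <- .bin_coupling(pre, method, cfg, idx = w$start[i]:w$end[i])
    coupling[i] <- mean(bc)
    maxbin[i] <- max(bc)
  }
  out <- cbind(w, coupling = coupling, max_bin_coupling = maxbin)
  attr(out, "bins") <- pre[[1]]$bins
  out
}

#' Permutation max-statistic significance threshold
#'
#' Builds the null distribution of the maximum band-bin coupling under random
#' re-pairing of trials: in each permutation the trial labels of the y
#' channel are shuffled (each trial's waveform preserved), band coupling is
#' recomputed per frequency bin (averaged over the plan's sub-windows), and
#' the maximum across bins is recorded. The threshold is the requested
#' percentile of these maxima and controls the family-wise error rate across
#' band bins; an observed max-bin coupling above it is significant.
#'
#' @param x,y [trial_window_set()]s holding the analysis trial set.
#' @param plan a [sliding_window_plan()] supplying the sub-windows, or NULL
#'   to treat the whole trial window as a single sub-window.
#' @param band `(low, high)` in Hz.
#' @param method `"coherence"` or `"mif_post"` (the latter is expensive:
#'   one k-NN MIF per bin per permutation).
#' @param cfg [estimator_config()] for the MIF method.
#' @param n_permutations number of permutations (>= 100; 5000 for a
#'   publication-grade threshold).
#' @param percentile null percentile defining the threshold (default 95).
#' @param seed RNG seed; identical seeds give identical thresholds.
#' @param tapers,demean as in [coupling_series()].
#' @return An object of class `"permutation_null"`: list with
#'   `null_max_samples`, `threshold`, `observed_max`, `observed_bin_coupling`,
#'   `bins`, `n_permutations`, `percentile`, `method`, `seed`.
#' @export
permutation_max_threshold <- function(x, y, plan = NULL, band = c(4, 8),
                                      method = c("coherence", "mif_post"),
                                      cfg = estimator_config(),
                                      n_permutations = 5000, percentile = 95,
                                      seed = NULL, tapers = NULL,
                                      demean = TRUE) {
  method <- match.arg(method)
  .check_tws(x); .check_tws(y)
  if (nrow(x$data) != nrow(y$data)) stop("x and y must have equal trial counts")
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  pre <- .band_increments(x, y, plan, band, tapers, demean)
  n <- nrow(x$data)
  obs_bins <- .bin_coupling(pre, method, cfg)
  null_max <- vapply(seq_len(n_permutations), function(p) {
    max(.bin_coupling(pre, method, cfg, perm = sample.int(n)))
  }, numeric(1))
  structure(list(null_max_samples = null_max,
                 threshold = unname(quantile(null_max, percentile / 100)),
                 observed_max = max(obs_bins),
                 observed_bin_coupling = obs_bins, bins = pre[[1]]$bins,
                 n_permutations = n_permutations, percentile = percentile,
                 method = method, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(paste0("<permutation_null> %s max-statistic, %d permutations: ",
                     "threshold (%gth pct) = %.4g, observed max = %.4g\n"),
              x$method, x$n_permutations, x$percentile, x$threshold,
              x$observed_max))
  invisible(x)
}

#' Moving-block bootstrap CI for a Pearson correlation
#'
#' Pearson correlation of two aligned series with a percentile confidence
#' interval from a circular moving-block bootstrap, which respects the
#' autocorrelation that overlapping sliding windows induce. Blocks of
#' `block_length` consecutive (x, y) pairs are resampled jointly with
#' wrap-around until the series length is reached.
#'
#' @param x_series,y_series equal-length numeric series (n >= 8) with nonzero
#'   variance.
#' @param block_length block length; default `ceiling(n^(1/3))`.
#' @param n_bootstrap bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `"correlation_result"`: list with `r`,
#'   `ci_low`, `ci_high`, `significant` (CI excludes 0), `n_windows`,
#'   `block_length`, `n_bootstrap`, `conf_level`.
#' @export
block_bootstrap_correlation <- function(x_series, y_series,
                                        block_length = NULL,
                                        n_bootstrap = 2000, seed = NULL,
                                        conf_level = 0.95) {
  x <- as.numeric(x_series)
  y <- as.numeric(y_series)
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n < 8) stop("need at least 8 windows")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance series")
  l <- as.integer(block_length %||% ceiling(n^(1 / 3)))
  if (l < 1 || l > n) stop("block_length must be in [1, n]")
  if (!is.null(seed)) set.seed(seed)
  r <- cor(x, y)
  nb <- ceiling(n / l)
  starts <- matrix(sample.int(n, nb * n_bootstrap, replace = TRUE), nb,
                   n_bootstrap)
  S <- starts[rep(seq_len(nb), each = l), , drop = FALSE]
  idx <- ((S + rep(0:(l - 1), times = nb) - 1) %% n) + 1
  idx <- idx[seq_len(n), , drop = FALSE]
  X <- matrix(x[idx], n); Y <- matrix(y[idx], n)
  mx <- colMeans(X); my <- colMeans(Y)
  cxy <- colMeans(X * Y) - mx * my
  vx <- colMeans(X^2) - mx^2
  vy <- colMeans(Y^2) - my^2
  rb <- ifelse(vx > 0 & vy > 0, cxy / sqrt(vx * vy), NA_real_)
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(rb, c(a, 1 - a), na.rm = TRUE))
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0, n_windows = n,
                 block_length = l, n_bootstrap = n_bootstrap,
                 conf_level = conf_level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(paste0("<correlation_result> r = %.3f, %g%% block-bootstrap CI ",
                     "[%.3f, %.3f]%s (n = %d windows, block = %d)\n"),
              x$r, 100 * x$conf_level, x$ci_low, x$ci_high,
              if (x$significant) " *" else "", x$n_windows, x$block_length))
  invisible(x)
}

#' Z-test for two dependent correlations sharing one variable
#'
#' Meng-Rosenthal-Rubin test comparing `r1 = cor(a, c)` against
#' `r2 = cor(b, c)` when both involve the common variable c (here: accuracy
#' correlated with two coupling measures), with `r_between = cor(a, b)`.
#' Two-tailed p from the standard normal.
#'
#' @param r1,r2 the two correlations with the common variable, in (-1, 1).
#' @param r_between correlation between the two non-common variables.
#' @param n number of paired observations (>= 4).
#' @return A list with `z` and `p_two_tailed`.
#' @export
dependent_correlation_ztest <- function(r1, r2, r_between, n) {
  rs <- c(r1, r2, r_between)
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly inside (-1, 1)")
  if (n < 4) stop("n must be at least 4")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  r2bar <- (r1^2 + r2^2) / 2
  f <- min((1 - r_between) / (2 * (1 - r2bar)), 1)
  h <- (1 - f * r2bar) / (1 - r2bar)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_between) * h))
  list(z = z, p_two_tailed = 2 * pnorm(-abs(z)))
}

#' End-to-end coupling vs accuracy analysis
#'
#' The full sliding-window pipeline: band-coupling series per trial window
#' ([coupling_series()]), a permutation max-statistic threshold computed from
#' the first window's trials ([permutation_max_threshold()]) and applied to
#' every window's max-bin coupling, per-window accuracy, and a moving-block
#' bootstrap CI for the Pearson correlation between (significance-tested)
#' coupling and accuracy. Windows failing the threshold have their coupling
#' zeroed by default before correlating; set `zero_subthreshold = FALSE` to
#' correlate raw values instead.
#'
#' @param x,y [trial_window_set()]s with whole trials.
#' @param accuracy per-trial 0/1 outcomes.
#' @param plan,band,method,cfg,tapers as in [coupling_series()].
#' @param n_permutations,percentile as in [permutation_max_threshold()].
#' @param zero_subthreshold zero out windows failing the threshold.
#' @param block_length,n_bootstrap as in [block_bootstrap_correlation()].
#' @param seed RNG seed for the permutations and the bootstrap.
#' @return A list with `windows` (per-window table: `start`, `end`,
#'   `coupling`, `max_bin_coupling`, `passed_threshold`, `coupling_used`,
#'   `accuracy`), `null` (the [permutation_max_threshold()] object) and
#'   `correlation` (a `correlation_result`, with `r = NA` if the tested
#'   coupling series is degenerate).
#' @export
task_coupling_analysis <- function(x, y, accuracy,
                                   plan = sliding_window_plan(),
                                   band = c(4, 8),
                                   method = c("coherence", "mif_post"),
                                   cfg = estimator_config(),
                                   n_permutations = 1000, percentile = 95,
                                   zero_subthreshold = TRUE,
                                   block_length = NULL, n_bootstrap = 2000,
                                   seed = NULL, tapers = NULL) {
  method <- match.arg(method)
  if (length(accuracy) != nrow(x$data)) {
    stop("accuracy length must match the trial count")
  }
  if (!is.null(seed)) set.seed(seed)
  cs <- coupling_series(x, y, plan, band, method, cfg, tapers)
  w1 <- seq_len(plan$window_size)
  xw <- trial_window_set(x$data[w1, , drop = FALSE], x$fs, x$t0)
  yw <- trial_window_set(y$data[w1, , drop = FALSE], y$fs, y$t0)
  null <- permutation_max_threshold(xw, yw, plan, band, method, cfg,
                                    n_permutations, percentile,
                                    seed = NULL, tapers = tapers)
  passed <- cs$max_bin_coupling > null$threshold
  used <- if (zero_subthreshold) ifelse(passed, cs$coupling, 0) else
    cs$coupling
  acc <- accuracy_series(accuracy, plan)
  corr <- if (sd(used) == 0 || sd(acc) == 0) {
    structure(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   significant = FALSE, n_windows = length(used),
                   block_length = NA_integer_, n_bootstrap = n_bootstrap,
                   conf_level = 0.95),
              class = "correlation_result")
  } else {
    block_bootstrap_correlation(used, acc, block_length, n_bootstrap,
                                seed = NULL)
  }
  windows <- cbind(cs, passed_threshold = passed, coupling_used = used,
                   accuracy = acc)
  list(windows = windows, null = null, correlation = corr)
}
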