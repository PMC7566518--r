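#' Benchmark estimator configurations
#'
#' The default grid of estimator/strategy combinations compared by the
#' benchmarks: the k-NN estimator under the three DPSS taper-combination
#' strategies plus the traditional single Hamming-taper comparator. Each
#' configuration is a list with `label`, an [estimator_config()] `cfg`,
#' `strategy` and `taper` (`"dpss"` or `"hamming"`).
#'
#' @param include_histograms also include the 2-bin fixed and 3-bin adaptive
#'   histogram comparators (post strategy).
#' @return A list of configuration lists.
#' @export
default_benchmark_configs <- function(include_histograms = FALSE) {
  cfgs <- list(
    list(label = "knn_naive", cfg = estimator_config("knn"),
         strategy = "naive", taper = "dpss"),
    list(label = "knn_pre", cfg = estimator_config("knn"),
         strategy = "pre", taper = "dpss"),
    list(label = "knn_post", cfg = estimator_config("knn"),
         strategy = "post", taper = "dpss"),
    list(label = "knn_hamming", cfg = estimator_config("knn"),
         strategy = "post", taper = "hamming"))
  if (include_histograms) {
    cfgs <- c(cfgs, list(
      list(label = "hist_fixed_post", cfg = estimator_config("hist_fixed"),
           strategy = "post", taper = "dpss"),
      list(label = "hist_adaptive_post",
           cfg = estimator_config("hist_adaptive"),
           strategy = "post", taper = "dpss")))
  }
  cfgs
}

# Shared Monte-Carlo engine: for each true MIF value, simulate n_paths
# Rayleigh-model paths and estimate MIF at (f0, f0) under every
# configuration. Returns an n_reps x n_configs estimate matrix. Per-rep seeds
# are derived deterministically from `seed` so runs are reproducible
# bit-for-bit and each rep is an independent stream.
.benchmark_estimates <- function(truths, n_paths, configs, seed,
                                 f0 = 8, fs = 128, n_samples = 128,
                                 nw = 2, n_tapers = 3) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, length(truths))
  dp <- generate_dpss(n_samples, nw, n_tapers)
  hm <- hamming_taper(n_samples)
  need_hamming <- any(vapply(configs, function(cf) cf$taper == "hamming",
                             logical(1)))
  est <- matrix(NA_real_, length(truths), length(configs),
                dimnames = list(NULL,
                                vapply(configs, `[[`, character(1), "label")))
  for (r in seq_along(truths)) {
    p <- sinusoid_model_params(f0 = f0, fs = fs, n_samples = n_samples,
                               n_paths = n_paths,
                               sigma_b = sigma_b_for_true_mif(truths[r]),
                               seed = rep_seeds[r])
    s <- simulate_random_sinusoids(p)
    xw <- condition_windows(s$x)
    yw <- condition_windows(s$y)
    IXd <- fourier_increment_samples(xw, dp, f0)$values
    IYd <- fourier_increment_samples(yw, dp, f0)$values
    if (need_hamming) {
      IXh <- fourier_increment_samples(xw, hm, f0)$values
      IYh <- fourier_increment_samples(yw, hm, f0)$values
    }
    for (ci in seq_along(configs)) {
      cf <- configs[[ci]]
      est[r, ci] <- if (cf$cfg$method == "oracle") {
        truths[r]
      } else if (cf$cfg$method == "constant") {
        1
      } else if (cf$taper == "hamming") {
        .mif_from_increments(IXh, IYh, cf$cfg, cf$strategy)
      } else {
        .mif_from_increments(IXd, IYd, cf$cfg, cf$strategy)
      }
    }
  }
  est
}

.cor_or_zero <- function(truths, est) {
  if (sd(est) == 0 || sd(truths) == 0) {
    list(rho = 0, degenerate = TRUE)
  } else {
    list(rho = cor(truths, est), degenerate = FALSE)
  }
}

#' Correlation-with-truth benchmark
#'
#' For each centre value, draws `n_reps` true MIF values uniformly in
#' `centre +/- half_range`, simulates `n_paths` Rayleigh-model paths at the
#' matching noise scale, estimates MIF at `(f0, f0)` under every
#' configuration, and reports the Pearson correlation between estimates and
#' truths. A perfect (zero-variance) estimator scores 1; a constant estimator
#' scores 0 and is flagged degenerate. Correlations may only be compared
#' across configurations, not across centres.
#'
#' @param centers true-MIF centres in nats; `centers - half_range` must stay
#'   positive.
#' @param half_range half-width of the uniform truth range around each centre.
#' @param n_reps Monte-Carlo repetitions per centre (>= 10).
#' @param n_paths sample paths (trials) per estimate.
#' @param configs configuration list, see [default_benchmark_configs()].
#' @param seed master seed; all per-rep seeds derive from it.
#' @param f0,fs,n_samples,nw,n_tapers model geometry and taper parameters.
#' @param return_estimates attach the raw estimate matrix and truths as
#'   attributes `"estimates"` and `"truths"` (lists indexed by centre).
#' @return A data frame with one row per (centre, configuration):
#'   `center_true_mi`, `estimator`, `strategy`, `taper`, `n_reps`,
#'   `correlation_with_truth`, `estimator_variance`, `degenerate`, `seed`.
#' @export
run_correlation_benchmark <- function(centers, half_range = 0.2,
                                      n_reps = 300, n_paths = 100,
                                      configs = default_benchmark_configs(),
                                      seed = 1, f0 = 8, fs = 128,
                                      n_samples = 128, nw = 2, n_tapers = 3,
                                      return_estimates = FALSE) {
  if (n_reps < 10) stop("n_reps must be at least 10 for a meaningful rho")
  if (any(centers - half_range <= 0)) {
    stop("centers - half_range must remain positive")
  }
  set.seed(seed)
  center_seeds <- sample.int(.Machine$integer.max, length(centers))
  rows <- list()
  est_list <- truth_list <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    set.seed(center_seeds[i])
    truths <- runif(n_reps, centers[i] - half_range, centers[i] + half_range)
    est <- .benchmark_estimates(truths, n_paths, configs, center_seeds[i],
                                f0, fs, n_samples, nw, n_tapers)
    est_list[[i]] <- est
    truth_list[[i]] <- truths
    for (ci in seq_along(configs)) {
      cf <- configs[[ci]]
      cz <- .cor_or_zero(truths, est[, ci])
      rows[[length(rows) + 1]] <- data.frame(
        center_true_mi = centers[i], estimator = cf$label,
        strategy = cf$strategy, taper = cf$taper, n_reps = n_reps,
        correlation_with_truth = cz$rho,
        estimator_variance = var(est[, ci]), degenerate = cz$degenerate,
        seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  if (return_estimates) {
    attr(out, "estimates") <- est_list
    attr(out, "truths") <- truth_list
  }
  out
}

#' Estimator-variance benchmark
#'
#' Holds the true MIF fixed at each centre (no range), repeats simulation and
#' estimation `n_reps` times, and reports the variance of the estimates per
#' configuration. Variances are only meaningful within an estimator family
#' (the `variance_comparable_within` column records the family); a constant
#' estimator has zero variance yet zero correlation with truth, so variance
#' must always be read together with [run_correlation_benchmark()].
#'
#' @inheritParams run_correlation_benchmark
#' @return A data frame with `center_true_mi`, `estimator`, `strategy`,
#'   `taper`, `n_reps`, `estimator_variance`, `estimator_mean`,
#'   `variance_comparable_within`, `seed`; raw estimates attached as for
#'   [run_correlation_benchmark()] when requested.
#' @export
run_variance_benchmark <- function(centers, n_reps = 300, n_paths = 100,
                                   configs = default_benchmark_configs(),
                                   seed = 1, f0 = 8, fs = 128,
                                   n_samples = 128, nw = 2, n_tapers = 3,
                                   return_estimates = FALSE) {
  if (n_reps < 10) stop("n_reps must be at least 10")
  if (any(centers <= 0)) stop("centers must be positive")
  set.seed(seed)
  center_seeds <- sample.int(.Machine$integer.max, length(centers))
  rows <- list()
  est_list <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    truths <- rep(centers[i], n_reps)
    est <- .benchmark_estimates(truths, n_paths, configs, center_seeds[i],
                                f0, fs, n_samples, nw, n_tapers)
    est_list[[i]] <- est
    for (ci in seq_along(configs)) {
      cf <- configs[[ci]]
      rows[[length(rows) + 1]] <- data.frame(
        center_true_mi = centers[i], estimator = cf$label,
        strategy = cf$strategy, taper = cf$taper, n_reps = n_reps,
        estimator_variance = var(est[, ci]),
        estimator_mean = mean(est[, ci]),
        variance_comparable_within = cf$cfg$method, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  if (return_estimates) attr(out, "estimates") <- est_list
  out
}

#' Asymptotic bias/variance benchmark
#'
#' Tracks the pre (k = 3) and post (k = n/2) k-NN estimators across sample
#' sizes at a fixed true MIF: the pre estimator's bias shrinks with sample
#' size while the post estimator trades bias for a much smaller variance that
#' also shrinks with sample size.
#'
#' @param sample_sizes increasing trial counts.
#' @param n_reps repetitions per size.
#' @param truth true MIF in nats (sets the model noise scale).
#' @param seed master seed.
#' @inheritParams run_correlation_benchmark
#' @return A data frame with one row per (size, estimator): `n_paths`,
#'   `estimator`, `mean`, `bias`, `variance`, `p5`, `p95`, `n_reps`, `truth`.
#' @export
run_asymptotic_benchmark <- function(sample_sizes = c(50, 100, 200, 400),
                                     n_reps = 300, truth = log(2), seed = 1,
                                     f0 = 8, fs = 128, n_samples = 128,
                                     nw = 2, n_tapers = 3) {
  if (is.unsorted(sample_sizes, strictly = TRUE)) {
    stop("sample_sizes must be strictly increasing")
  }
  if (sample_sizes[1] <= 4) stop("smallest sample size too small for k = 3")
  configs <- list(
    list(label = "pre_k3",
         cfg = estimator_config("knn", k_rule = "fixed", k_fixed = 3),
         strategy = "pre", taper = "dpss"),
    list(label = "post_khalf",
         cfg = estimator_config("knn", k_rule = "half_samples"),
         strategy = "post", taper = "dpss"))
  set.seed(seed)
  size_seeds <- sample.int(.Machine$integer.max, length(sample_sizes))
  rows <- list()
  for (i in seq_along(sample_sizes)) {
    est <- .benchmark_estimates(rep(truth, n_reps), sample_sizes[i], configs,
                                size_seeds[i], f0, fs, n_samples, nw,
                                n_tapers)
    for (ci in seq_along(configs)) {
      e <- est[, ci]
      rows[[length(rows) + 1]] <- data.frame(
        n_paths = sample_sizes[i], estimator = configs[[ci]]$label,
        mean = mean(e), bias = mean(e) - truth, variance = var(e),
        p5 = unname(quantile(e, 0.05)), p95 = unname(quantile(e, 0.95)),
        n_reps = n_reps, truth = truth)
    }
  }
  do.call(rbind, rows)
}
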