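#' Random-sinusoid model parameters
#'
#' Parameters of the two-channel random-sinusoid model
#' \deqn{X(t) = A\cos(2\pi f_0 t + \Theta),\quad
#'       W(t) = B\cos(2\pi f_0 t + \Phi),\quad Y(t) = X(t) + W(t)}
#' with amplitudes and phases drawn independently once per trial. Under the
#' `"rayleigh"` family, \eqn{A \sim Rayleigh(1)}, \eqn{B \sim Rayleigh(\sigma_B)}
#' and \eqn{\Theta,\Phi \sim Uniform(0, 2\pi)}; every marginal of the process
#' is then Gaussian and the mutual information in frequency between X and Y at
#' \eqn{f_0} has the closed form of [true_mif_gp()]. Under the `"uniform"`
#' family, \eqn{A, B \sim Uniform(-a, a)} (default half-width 0.5), which makes
#' the process non-Gaussian (marginal kurtosis 2.7 instead of 3).
#'
#' The default geometry (`n_samples = 128`, `fs = 128`, `f0 = 8`) places
#' `f0` exactly on an FFT bin; path length and `f0` are otherwise arbitrary
#' because only the number of paths controls estimator sample size.
#'
#' @param f0 oscillation frequency in Hz; must be below Nyquist.
#' @param fs sampling rate in Hz.
#' @param n_samples samples per path (>= 8).
#' @param n_paths number of sample paths / trials (>= 2).
#' @param sigma_b Rayleigh scale of the noise amplitude B (Rayleigh family
#'   only). `sigma_b = 0` is the noiseless limit W = 0, Y = X.
#' @param amplitude_family `"rayleigh"` (Gaussian process) or `"uniform"`
#'   (non-Gaussian process).
#' @param uniform_halfwidth half-width of the uniform amplitude distribution.
#' @param seed optional integer RNG seed; identical seeds reproduce paths
#'   bit-for-bit.
#' @return An object of class `"sinusoid_model_params"`.
#' @export
sinusoid_model_params <- function(f0 = 8, fs = 128, n_samples = 128,
                                  n_paths = 100, sigma_b = 1,
                                  amplitude_family = c("rayleigh", "uniform"),
                                  uniform_halfwidth = 0.5, seed = NULL) {
  amplitude_family <- match.arg(amplitude_family)
  if (f0 >= fs / 2) stop("f0 must be below the Nyquist frequency fs/2")
  if (f0 <= 0) stop("f0 must be positive")
  if (n_samples < 8) stop("n_samples must be at least 8")
  if (n_paths < 2) stop("n_paths must be at least 2")
  if (amplitude_family == "rayleigh" && sigma_b < 0) {
    stop("sigma_b must be non-negative for the rayleigh family")
  }
  if (amplitude_family == "uniform" && uniform_halfwidth <= 0) {
    stop("uniform_halfwidth must be positive")
  }
  structure(list(f0 = f0, fs = fs, n_samples = as.integer(n_samples),
                 n_paths = as.integer(n_paths), sigma_b = sigma_b,
                 amplitude_family = amplitude_family,
                 uniform_halfwidth = uniform_halfwidth, seed = seed),
            class = "sinusoid_model_params")
}

# Rayleigh(sigma) draws via inverse transform.
.rrayleigh <- function(n, sigma) sigma * sqrt(2 * rexp(n))

#' Simulate paths of the random-sinusoid model
#'
#' Draws `n_paths` independent sample paths of the two channels X and
#' Y = X + W described in [sinusoid_model_params()]. One amplitude/phase draw
#' per path; the model has no within-path dynamics.
#'
#' @param params a [sinusoid_model_params()] object.
#' @return A list with elements `x` and `y` ([trial_window_set()]s sharing the
#'   sampling rate) and `params`.
#' @examples
#' s <- simulate_random_sinusoids(sinusoid_model_params(n_paths = 10, seed = 1))
#' dim(s$x$data)
#' @export
simulate_random_sinusoids <- function(params) {
  if (!inherits(params, "sinusoid_model_params")) {
    stop("params must come from sinusoid_model_params()")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_paths
  if (params$amplitude_family == "rayleigh") {
    A <- .rrayleigh(n, 1)
    B <- if (params$sigma_b > 0) .rrayleigh(n, params$sigma_b) else numeric(n)
  } else {
    hw <- params$uniform_halfwidth
    A <- runif(n, -hw, hw)
    B <- runif(n, -hw, hw)
  }
  Theta <- runif(n, 0, 2 * pi)
  Phi <- runif(n, 0, 2 * pi)
  tt <- (seq_len(params$n_samples) - 1) / params$fs
  ang <- 2 * pi * params$f0 * tt
  X <- A * cos(outer(Theta, ang, `+`))
  W <- B * cos(outer(Phi, ang, `+`))
  list(x = trial_window_set(X, params$fs),
       y = trial_window_set(X + W, params$fs),
       params = params)
}

#' Simulate independent white-noise channels
#'
#' Convenience generator for null data: two channels of i.i.d. Gaussian noise
#' with no dependence within or between channels.
#'
#' @param n_paths,n_samples,fs geometry as in [sinusoid_model_params()].
#' @param sd noise standard deviation.
#' @param seed optional RNG seed.
#' @return A list with `x` and `y` [trial_window_set()]s.
#' @export
simulate_white_noise <- function(n_paths, n_samples, fs, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(x = trial_window_set(matrix(rnorm(n_paths * n_samples, sd = sd),
                                   n_paths, n_samples), fs),
       y = trial_window_set(matrix(rnorm(n_paths * n_samples, sd = sd),
                                   n_paths, n_samples), fs))
}

#' Analytic MIF of the Rayleigh-amplitude model
#'
#' For the Rayleigh (Gaussian-process) family, the true mutual information in
#' frequency between X and Y at the oscillation frequency is
#' \deqn{MI(f_0, f_0) = \log(1 + 1/\sigma_B^2)} nats; at every other
#' frequency pair the true MIF of the underlying process is zero.
#'
#' @param sigma_b Rayleigh scale of the noise amplitude (positive; vectorized).
#' @return MIF in nats.
#' @examples
#' true_mif_gp(1)          # log(2)
#' true_mif_gp(1 / sqrt(exp(1) - 1))  # 1 nat
#' @export
true_mif_gp <- function(sigma_b) {
  if (any(sigma_b <= 0)) stop("sigma_b must be positive")
  log1p(1 / sigma_b^2)
}

#' Noise scale achieving a target true MIF
#'
#' Inverse of [true_mif_gp()]: the Rayleigh scale \eqn{\sigma_B} for which the
#' Rayleigh-amplitude model's true MIF at \eqn{(f_0, f_0)} equals `mi` nats.
#' Used by the benchmarks to sweep ranges of true MIF values.
#'
#' @param mi target MIF in nats (positive; vectorized).
#' @return Positive scale \eqn{\sigma_B = 1/\sqrt{e^{mi} - 1}}.
#' @export
sigma_b_for_true_mif <- function(mi) {
  if (any(mi <= 0)) stop("mi must be positive")
  1 / sqrt(expm1(mi))
}

#' Analytic marginal kurtosis of the sinusoid models
#'
#' Fourth standardized moment of the marginal \eqn{X(t) = A\cos(2\pi f_0 t +
#' \Theta)} with \eqn{\Theta} uniform: by independence of amplitude and phase,
#' \eqn{E[X^4]/E[X^2]^2 = \tfrac{3}{2}\, E[A^4]/E[A^2]^2}. The Rayleigh family
#' gives 3 (a Gaussian marginal), the uniform family 2.7 (non-Gaussian),
#' independently of the scale.
#'
#' @param amplitude_family `"rayleigh"` or `"uniform"`.
#' @return The kurtosis (dimensionless).
#' @export
analytic_kurtosis <- function(amplitude_family = c("rayleigh", "uniform")) {
  amplitude_family <- match.arg(amplitude_family)
  # amplitude moment ratio E[A^4] / E[A^2]^2 for each family (scale-free)
  ratio <- switch(amplitude_family,
                  rayleigh = 8 / 2^2,          # E[A^2]=2s^2, E[A^4]=8s^4
                  uniform = (1 / 5) / (1 / 3)^2) # E[A^2]=a^2/3, E[A^4]=a^4/5
  # cosine moments: E[cos^2]=1/2, E[cos^4]=3/8  =>  factor 3/2
  1.5 * ratio
}

#' Synthetic task-session parameters
#'
#' Parameters of a synthetic two-channel session emulating the structure of a
#' trialized visual task recording: each trial carries a shared band-limited
#' oscillation whose inter-channel coupling drifts across trials, and a binary
#' accuracy outcome whose success probability is tied to that trial's
#' coupling. This is a stand-in generator for real cortical sessions; see the
#' methods vignette for what it does and does not emulate.
#'
#' @param n_trials number of trials (>= 120 so that 100-trial sliding windows
#'   have room to slide).
#' @param fs sampling rate in Hz. The default 120 Hz makes 0.3 s sub-windows
#'   exactly 36 samples long.
#' @param trial_length_s trial duration in seconds.
#' @param band theta-like frequency band `(low, high)` in Hz.
#' @param coupling_profile per-trial target coupling (squared inter-channel
#'   correlation of the oscillatory component) in `[0, 1)`. Default: a smooth
#'   rising drift from 0.2 to 0.7 with a small oscillation, mimicking
#'   learning-related change across a session.
#' @param accuracy_link logistic slope linking a trial's coupling (centred on
#'   the session mean) to its success probability.
#' @param base_accuracy session-mean success probability.
#' @param osc_freq frequency of the shared oscillation in Hz; the default
#'   20/3 Hz sits on the frequency grid of a 0.3 s sub-window and inside the
#'   default band.
#' @param noise_sd standard deviation of the independent broadband noise added
#'   to each channel.
#' @param seed optional RNG seed.
#' @return An object of class `"task_session_params"`.
#' @export
task_session_params <- function(n_trials = 400, fs = 120, trial_length_s = 3.6,
                                band = c(4, 8), coupling_profile = NULL,
                                accuracy_link = 4, base_accuracy = 0.75,
                                osc_freq = 20 / 3, noise_sd = 0.5,
                                seed = NULL) {
  if (n_trials < 120) stop("n_trials must be at least 120")
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2]) {
    stop("band must be (low, high) with 0 < low < high < fs/2")
  }
  if (osc_freq <= 0 || osc_freq >= fs / 2) stop("osc_freq outside (0, fs/2)")
  if (is.null(coupling_profile)) {
    i <- seq_len(n_trials)
    coupling_profile <- 0.2 + 0.5 * (i - 1) / (n_trials - 1) +
      0.05 * sin(4 * pi * i / n_trials)
    coupling_profile <- pmin(pmax(coupling_profile, 0.02), 0.95)
  }
  if (length(coupling_profile) != n_trials ||
      any(coupling_profile < 0) || any(coupling_profile >= 1)) {
    stop("coupling_profile must have one value in [0, 1) per trial")
  }
  structure(list(n_trials = as.integer(n_trials), fs = fs,
                 trial_length_s = trial_length_s, band = band,
                 coupling_profile = coupling_profile,
                 accuracy_link = accuracy_link,
                 base_accuracy = base_accuracy, osc_freq = osc_freq,
                 noise_sd = noise_sd, seed = seed),
            class = "task_session_params")
}

#' Simulate a synthetic task session
#'
#' Generates two channels whose shared oscillatory component has per-trial
#' coupling following `coupling_profile`, plus a per-trial binary accuracy
#' series linked to coupling through a logistic model. The oscillation is a
#' random-phase sinusoid at `osc_freq` with Rayleigh(1) amplitude; channel Y's
#' oscillatory component is \eqn{\sqrt{c_i}} times channel X's plus an
#' independent copy scaled by \eqn{\sqrt{1 - c_i}}, so the squared
#' inter-channel correlation of the oscillation in trial i equals the profile
#' value \eqn{c_i}. Independent Gaussian noise is added to both channels.
#'
#' @param params a [task_session_params()] object.
#' @return A list with `x`, `y` ([trial_window_set()]s), `accuracy` (0/1
#'   vector), `p_correct` (the generating success probabilities) and `params`.
#' @export
simulate_task_session <- function(params) {
  if (!inherits(params, "task_session_params")) {
    stop("params must come from task_session_params()")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_trials
  ns <- round(params$trial_length_s * params$fs)
  cp <- params$coupling_profile
  rho <- sqrt(cp)
  # complex oscillation amplitudes: u1 drives X, a rho-mixture drives Y
  u1 <- .rrayleigh(n, 1) * exp(1i * runif(n, 0, 2 * pi))
  u2 <- .rrayleigh(n, 1) * exp(1i * runif(n, 0, 2 * pi))
  uy <- rho * u1 + sqrt(1 - rho^2) * u2
  tt <- (seq_len(ns) - 1) / params$fs
  carrier <- exp(1i * 2 * pi * params$osc_freq * tt)
  X <- Re(u1 %o% carrier) + matrix(rnorm(n * ns, sd = params$noise_sd), n, ns)
  Y <- Re(uy %o% carrier) + matrix(rnorm(n * ns, sd = params$noise_sd), n, ns)
  p <- plogis(qlogis(params$base_accuracy) +
                params$accuracy_link * (cp - mean(cp)))
  acc <- rbinom(n, 1L, p)
  list(x = trial_window_set(X, params$fs),
       y = trial_window_set(Y, params$fs),
       accuracy = acc, p_correct = p, params = params)
}

#' Export a simulated session as delimited text
#'
#' Writes one trial-matrix file per channel (see [write_trial_matrix()]) and a
#' one-column accuracy file.
#'
#' @param session output of [simulate_task_session()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_session <- function(session, dir, prefix = "session") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  px <- file.path(dir, paste0(prefix, "_x.txt"))
  py <- file.path(dir, paste0(prefix, "_y.txt"))
  pa <- file.path(dir, paste0(prefix, "_accuracy.txt"))
  write_trial_matrix(session$x, px)
  write_trial_matrix(session$y, py)
  writeLines(as.character(session$accuracy), pa)
  invisible(c(x = px, y = py, accuracy = pa))
}
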