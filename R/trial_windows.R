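#' Trialized window set
#'
#' Container for a set of equal-length windows ("trials") of one channel:
#' a trials x samples real matrix plus its sampling rate. Windows are assumed
#' mutually independent realizations of the same process, e.g. recordings
#' aligned to a stimulus across trials of an experiment.
#'
#' @param data numeric matrix, one row per trial, one column per time sample.
#' @param fs sampling rate in Hz (positive scalar).
#' @param t0 start time of the window relative to the trial reference, in
#'   seconds. Only used for bookkeeping when cutting sub-windows.
#'
#' @return An object of class `"trial_window_set"`: a list with elements
#'   `data`, `fs`, `t0`.
#' @examples
#' w <- trial_window_set(matrix(rnorm(40), 5, 8), fs = 8)
#' n_trials(w)
#' @export
trial_window_set <- function(data, fs, t0 = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("trial data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  structure(list(data = data, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "trial_window_set")
}

#' @export
print.trial_window_set <- function(x, ...) {
  cat(sprintf("<trial_window_set> %d trials x %d samples @ %g Hz (t0 = %g s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0))
  invisible(x)
}

#' @rdname trial_window_set
#' @param w a `trial_window_set`.
#' @export
n_trials <- function(w) nrow(w$data)

#' @rdname trial_window_set
#' @export
n_samples <- function(w) ncol(w$data)

.check_tws <- function(w, arg = deparse(substitute(w))) {
  if (!inherits(w, "trial_window_set")) {
    stop(sprintf("%s must be a trial_window_set", arg))
  }
  invisible(w)
}

#' Remove the per-window mean
#'
#' Subtracts each trial's mean from that trial, so that no DC component leaks
#' into low-frequency bins when the window is tapered. Idempotent; shape,
#' sampling rate and t0 are preserved.
#'
#' @param w a [trial_window_set()].
#' @return A `trial_window_set` whose rows all have mean zero.
#' @export
condition_windows <- function(w) {
  .check_tws(w)
  d <- w$data - rowMeans(w$data)
  trial_window_set(d, w$fs, w$t0)
}

#' Extract a sub-window of every trial
#'
#' Cuts the samples falling in `[start_s, start_s + length_s)` (relative to
#' the trial reference) out of every trial.
#'
#' @param w a [trial_window_set()].
#' @param start_s sub-window start time in seconds.
#' @param length_s sub-window length in seconds.
#' @return A `trial_window_set` with `round(length_s * fs)` samples per trial
#'   and `t0 = start_s`.
#' @export
subwindow <- function(w, start_s, length_s) {
  .check_tws(w)
  i0 <- round((start_s - w$t0) * w$fs) + 1L
  len <- round(length_s * w$fs)
  if (len < 1L) stop("sub-window shorter than one sample")
  if (i0 < 1L || i0 + len - 1L > ncol(w$data)) {
    stop(sprintf("sub-window [%g, %g) s falls outside the trial window",
                 start_s, start_s + length_s))
  }
  trial_window_set(w$data[, i0:(i0 + len - 1L), drop = FALSE], w$fs, start_s)
}
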