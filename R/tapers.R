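#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Generates the first `n_tapers` DPSS sequences of length `n_samples` with
#' time-half-bandwidth product `nw`, as the eigenvectors of the standard
#' symmetric tridiagonal Slepian matrix. Tapers are orthonormal and ordered by
#' decreasing spectral concentration; the concentration eigenvalues are
#' computed independently from the sinc (Toeplitz) concentration matrix, so
#' they can serve as a check on taper quality.
#'
#' By convention at most `floor(2 * nw) - 1` tapers are returned, since higher
#' orders lose spectral concentration rapidly; pass `allow_excess = TRUE` to
#' override.
#'
#' @param n_samples taper length N (>= 8).
#' @param nw time-half-bandwidth product (typically 2-4).
#' @param n_tapers number of tapers K (default `floor(2 * nw) - 1`).
#' @param allow_excess allow K to exceed `floor(2 * nw) - 1`.
#' @return An object of class `"taper_set"`: list with `tapers` (K x N matrix,
#'   one taper per row, rows orthonormal), `nw`, `concentrations` (K in-band
#'   energy fractions in (0, 1]) and `type = "dpss"`.
#' @examples
#' ts <- generate_dpss(64, nw = 3, n_tapers = 5)
#' round(ts$concentrations, 6)
#' @export
generate_dpss <- function(n_samples, nw = 2, n_tapers = floor(2 * nw) - 1,
                          allow_excess = FALSE) {
  if (n_samples < 8) stop("n_samples must be at least 8")
  if (nw <= 0) stop("nw must be positive")
  kmax <- floor(2 * nw) - 1
  if (n_tapers < 1) stop("n_tapers must be at least 1")
  if (n_tapers > kmax && !allow_excess) {
    stop(sprintf(paste0("n_tapers = %d exceeds the concentration limit ",
                        "floor(2*nw) - 1 = %d (set allow_excess = TRUE ",
                        "to override)"), n_tapers, kmax))
  }
  N <- as.integer(n_samples)
  W <- nw / N
  i <- 0:(N - 1)
  # symmetric tridiagonal matrix commuting with the concentration operator
  diag_main <- ((N - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  A <- matrix(0, N, N)
  A[cbind(i + 1, i + 1)] <- diag_main
  A[cbind(1:(N - 1), 2:N)] <- off
  A[cbind(2:N, 1:(N - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(n_tapers), drop = FALSE]
  # deterministic sign convention: positive mean for symmetric tapers,
  # positive initial slope for antisymmetric ones
  for (k in seq_len(n_tapers)) {
    s <- sum(V[, k])
    if (abs(s) > 1e-7) {
      if (s < 0) V[, k] <- -V[, k]
    } else if (V[2, k] - V[1, k] < 0) {
      V[, k] <- -V[, k]
    }
  }
  # concentration eigenvalues from the sinc Toeplitz matrix
  dmat <- outer(i, i, `-`)
  S <- sin(2 * pi * W * dmat) / (pi * dmat)
  diag(S) <- 2 * W
  conc <- vapply(seq_len(n_tapers),
                 function(k) drop(crossprod(V[, k], S %*% V[, k])),
                 numeric(1))
  structure(list(tapers = t(V), nw = nw, concentrations = conc,
                 type = "dpss"),
            class = "taper_set")
}

#' Single Hamming-window taper
#'
#' The traditional single-taper comparator: one Hamming window, normalized to
#' unit energy so it is commensurate with DPSS tapers. With a single taper the
#' naive, pre and post combination strategies coincide.
#'
#' @param n_samples taper length.
#' @return A `"taper_set"` with one row and `type = "hamming"`.
#' @export
hamming_taper <- function(n_samples) {
  if (n_samples < 8) stop("n_samples must be at least 8")
  n <- 0:(n_samples - 1)
  h <- 0.54 - 0.46 * cos(2 * pi * n / (n_samples - 1))
  h <- h / sqrt(sum(h^2))
  structure(list(tapers = matrix(h, 1), nw = NA_real_,
                 concentrations = NA_real_, type = "hamming"),
            class = "taper_set")
}

#' @export
print.taper_set <- function(x, ...) {
  cat(sprintf("<taper_set> %d %s taper(s) of length %d",
              nrow(x$tapers), x$type, ncol(x$tapers)))
  if (!is.na(x$nw)) cat(sprintf(" (nw = %g)", x$nw))
  cat("\n")
  invisible(x)
}

.check_tapers <- function(t, n_samples = NULL) {
  if (!inherits(t, "taper_set")) stop("expected a taper_set")
  if (!is.null(n_samples) && ncol(t$tapers) != n_samples) {
    stop(sprintf("taper length %d does not match window length %d",
                 ncol(t$tapers), n_samples))
  }
  invisible(t)
}
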