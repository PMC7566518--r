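# Shared fixtures built in code.

# Small Rayleigh-model channel pair.
gp_paths <- function(n_paths = 200, sigma_b = 1, seed = 1, ...) {
  simulate_random_sinusoids(
    sinusoid_model_params(n_paths = n_paths, sigma_b = sigma_b, seed = seed,
                          ...))
}

# A rectangular (all-ones) single taper, for discrete Fourier identities.
rect_taper <- function(n_samples) {
  structure(list(tapers = matrix(1, 1, n_samples), nw = NA_real_,
                 concentrations = NA_real_, type = "rect"),
            class = "taper_set")
}

# Single-row taper_set from row k of an existing set.
single_taper <- function(ts, k) {
  structure(list(tapers = ts$tapers[k, , drop = FALSE], nw = ts$nw,
                 concentrations = ts$concentrations[k], type = ts$type),
            class = "taper_set")
}
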