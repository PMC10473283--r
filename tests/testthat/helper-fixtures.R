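# Small programmatic fixtures shared across test files.

# random symmetric streamline-count connectome (raw)
toy_connectome <- function(n = 6, seed = 1, density = 0.6, max_count = 50) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  W[up] <- stats::rbinom(sum(up), 1, density) *
    sample.int(max_count, sum(up), replace = TRUE)
  W + t(W)
}

# fast simulation settings: short observation, short burn-in
quick_params <- function(...) {
  jr_params(T = 2, burn_in = 0.5, ...)
}

# alpha-band-limited noise (independent narrowband source), unit variance
narrowband_noise <- function(n, fs = 250, band = c(8, 13), seed = 1) {
  set.seed(seed)
  x <- bandpass_fft(stats::rnorm(n), band[1], band[2], fs)
  x / stats::sd(x)
}

# tiny normalized connectome + geometry pair for network simulations (n >= 4)
toy_network <- function(n = 6, seed = 2) {
  g <- synth_geometry(n, seed = seed)
  spec <- synth_cohort_spec(n_subjects = 1, n_regions = n)
  sc <- sc_normalize(synth_connectomes(spec, g, seed = seed + 1)[[1]])
  list(sc = sc, geometry = g)
}
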