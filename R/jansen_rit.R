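#' Jansen-Rit model parameters
#'
#' Builds the full parameter set for a network of delay-coupled Jansen-Rit
#' neural masses. Defaults are the standard alpha-generating operating point
#' of the model: excitatory/inhibitory synaptic gains `A`/`B` in mV, lumped
#' rate constants `beta_e`/`beta_i` in 1/s, intra-mass connectivity constants
#' `C = 135 * c(1, 0.8, 0.25, 0.25)`, sigmoid maximum rate `nu` (1/s),
#' threshold `theta` (mV) and slope `r` (1/mV), and a constant pulse-density
#' input `P` delivered to every pyramidal population.
#'
#' The stochastic drive is uncorrelated Gaussian noise on the pyramidal
#' pathway only: at every integration step the external input to mass `i` is
#' `P + noise_sd * eta` with `eta ~ N(0,1)` redrawn per mass per step and held
#' constant within the step. This per-step forcing is additive white noise of
#' effective intensity `noise_sd * sqrt(h)`; its accumulated contribution to
#' the state update scales with `sqrt(h)`.
#'
#' @param A,B Excitatory / inhibitory synaptic gain (mV).
#' @param beta_e,beta_i Excitatory / inhibitory lumped rate constants (1/s).
#' @param C Length-4 intra-mass connectivity constants (C1..C4).
#' @param nu Maximum firing rate of the sigmoid (1/s).
#' @param theta Sigmoid threshold potential (mV).
#' @param r Sigmoid slope (1/mV).
#' @param P Constant external input (pulse density, dimensionless).
#' @param noise_sd Standard deviation of the per-step Gaussian drive
#'   fluctuation (same units as `P`).
#' @param h Integration step (s). `1/h` must be an integer multiple of `fs`.
#' @param fs Output sample rate (Hz) after decimation.
#' @param T Observation time (s); `T * fs` must be a whole number of samples.
#' @param burn_in Discarded initial transient (s).
#' @param velocity Axonal conduction velocity (m/s) used to turn centroid
#'   distances into delays.
#' @param ... Overrides for any of the above by name.
#'
#' @return A list of class `jr_params`.
#' @examples
#' p <- jr_params(T = 2, burn_in = 0.5)
#' p$fs
#' @export
jr_params <- function(A = 3.25, B = 22, beta_e = 100, beta_i = 50,
                      C = 135 * c(1, 0.8, 0.25, 0.25),
                      nu = 5, theta = 6, r = 0.56, P = 150,
                      noise_sd = 30, h = 1e-4, fs = 1250,
                      T = 20, burn_in = 2, velocity = 10, ...) {
  p <- list(A = A, B = B, beta_e = beta_e, beta_i = beta_i, C = C,
            nu = nu, theta = theta, r = r, P = P, noise_sd = noise_sd,
            h = h, fs = fs, T = T, burn_in = burn_in, velocity = velocity)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  validate_jr_params(structure(p, class = "jr_params"))
}

validate_jr_params <- function(p) {
  stopifnot(length(p$C) == 4)
  pos <- c("A", "B", "beta_e", "beta_i", "nu", "r", "h", "fs", "velocity")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive scalar")
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$T <= 0 || p$burn_in < 0) stop("T must be > 0 and burn_in >= 0")
  decim <- 1 / (p$h * p$fs)
  if (abs(decim - round(decim)) > 1e-9)
    stop("fs must divide 1/h exactly (decimation factor must be an integer)")
  S <- p$T * p$fs
  if (abs(S - round(S)) > 1e-6)
    stop("T * fs must be an integer number of samples")
  p
}

#' Population firing-rate sigmoid
#'
#' `S(v) = nu / (1 + exp(r * (theta - v)))`: strictly increasing map from
#' mean membrane potential (mV) to mean firing rate (1/s), saturating at
#' `nu`, with `S(theta) = nu / 2`.
#'
#' @param v Membrane potential(s), mV.
#' @param params A [jr_params()] object (or any list with `nu`, `r`, `theta`).
#' @return Firing rate(s), 1/s.
#' @examples
#' jr_sigmoid(6, jr_params())  # midpoint: nu/2 = 2.5
#' @export
jr_sigmoid <- function(v, params = jr_params()) {
  params$nu / (1 + exp(params$r * (params$theta - v)))
}

#' Simulate a delay-coupled Jansen-Rit network
#'
#' Integrates `N` Jansen-Rit masses coupled through a normalized structural
#' connectome with distance-dependent conduction delays, using a stochastic
#' fourth-order Runge-Kutta scheme at step `params$h`. Delayed pyramidal
#' firing rates are read from a ring buffer at integration resolution
#' (delays rounded to the nearest step; pre-simulation history equals the
#' all-zero initial state). The burn-in is discarded and the pyramidal output
#' `v = y1 - y2` is decimated by stride `1/(h*fs)` to `fs` Hz.
#'
#' @param sc A normalized [connectome()] (entries in `[0, 1]`), or a bare
#'   weight matrix. Use `NULL` (with `n_regions`) for uncoupled masses.
#' @param geometry A [region_geometry()] providing the delay matrix, or
#'   `NULL` for zero delays.
#' @param params A [jr_params()] object.
#' @param K Global coupling scalar multiplying all long-range weights.
#' @param seed Integer seed; the only source of randomness is the noise
#'   stream, so identical seeds give bit-identical output.
#' @param n_regions Number of masses when `sc` is `NULL`.
#' @param blow_bound Abort threshold on `|v|` (mV); exceeding it signals an
#'   error (coupling too strong or step too large).
#' @param init Initial mass states: `"random"` (default) draws a seeded
#'   Gaussian state per mass (potentials sd 5 mV, derivatives sd 300 mV/s)
#'   so that after the burn-in every mass sits at an independent phase of
#'   its limit cycle; `"zero"` starts all states at 0 (which leaves
#'   identically driven masses phase-locked for a long time — useful for
#'   symmetry tests, misleading for connectivity estimates); or a `6 x N`
#'   numeric state matrix.
#'
#' @return A `region_ts`: an `S x N` matrix (time in rows, `S = T * fs`)
#'   with attributes `fs`, `K` and `seed`.
#' @examples
#' p <- jr_params(T = 1, burn_in = 0.2, noise_sd = 0)
#' ts <- jr_simulate(NULL, NULL, p, K = 0, seed = 1, n_regions = 1)
#' dim(ts)
#' @export
jr_simulate <- function(sc = NULL, geometry = NULL, params = jr_params(),
                        K = 0, seed = NULL, n_regions = NULL,
                        blow_bound = 1e6, init = c("random", "zero")) {
  if (is.null(sc)) {
    if (is.null(n_regions)) stop("supply `sc` or `n_regions`")
    W <- matrix(0, n_regions, n_regions)
  } else if (inherits(sc, "connectome")) {
    if (!sc$normalized && K != 0)
      stop("`sc` must be normalized before simulation (see sc_normalize())")
    W <- sc$weights
  } else {
    W <- as.matrix(sc)
  }
  N <- nrow(W)
  if (ncol(W) != N) stop("weight matrix must be square")

  if (is.null(geometry)) {
    dsteps <- matrix(0L, N, N)
  } else {
    if (nrow(geometry$delay) != N)
      stop("geometry and connectome disagree on the number of regions")
    dsteps <- matrix(as.integer(round(geometry$delay / params$h)), N, N)
  }

  decim <- as.integer(round(1 / (params$h * params$fs)))
  n_record <- as.integer(round(params$T * params$fs))
  burn_steps <- as.integer(round(params$burn_in / params$h))

  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(init)) {
    if (!identical(dim(init), c(6L, N))) stop("init must be 6 x N")
    init_m <- init
  } else {
    init <- match.arg(init)
    init_m <- if (init == "zero") matrix(0, 6, N)
    else rbind(matrix(stats::rnorm(3 * N, sd = 5), 3, N),
               matrix(stats::rnorm(3 * N, sd = 300), 3, N))
  }
  res <- jr_integrate_cpp(W, dsteps, K, unclass(params), n_record,
                          burn_steps, decim, blow_bound, init_m)
  if (!res$ok)
    stop("simulation blew up at integration step ", res$bad_step,
         " (|v| > ", blow_bound,
         "): coupling too strong or step too large", call. = FALSE)
  region_ts(res$v, fs = params$fs, K = K, seed = seed)
}

#' Region time-series container
#'
#' @param data `S x N` numeric matrix, time in rows.
#' @param fs Sample rate (Hz).
#' @param K,seed Optional provenance attributes.
#' @return A `region_ts` matrix.
#' @export
region_ts <- function(data, fs, K = NA_real_, seed = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) stop("non-finite values in series")
  structure(data, fs = fs, K = K, seed = if (is.null(seed)) NA else seed,
            class = c("region_ts", "matrix", "array"))
}

#' @export
print.region_ts <- function(x, ...) {
  cat("<region_ts> ", ncol(x), " regions x ", nrow(x), " samples @ ",
      attr(x, "fs"), " Hz\n", sep = "")
  invisible(x)
}

#' Run an ensemble of independent simulations
#'
#' Repeats [jr_simulate()] `n_runs` times with seeds `base_seed + 0:(n_runs-1)`
#' (order-stable, reproducible). Averaging functional connectivity over such
#' an ensemble suppresses the stochastic variability of single runs.
#'
#' @inheritParams jr_simulate
#' @param n_runs Number of runs (default 20).
#' @param base_seed Seed of the first run.
#' @return A list of `region_ts`.
#' @export
jr_ensemble <- function(sc, geometry, params = jr_params(), K = 0,
                        n_runs = 20, base_seed = 1, ...) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs) - 1L,
         function(r) jr_simulate(sc, geometry, params, K,
                                 seed = base_seed + r, ...))
}

#' Welch-averaged power spectral density
#'
#' Splits the series into 50%-overlapping Hann-windowed segments, averages
#' their periodograms, and returns one-sided power estimates. Used to locate
#' the dominant spectral peak of simulated activity.
#'
#' @param x Numeric vector.
#' @param fs Sample rate (Hz).
#' @param segment Segment length in samples (default 4096).
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, segment = 4096) {
  n <- length(x)
  segment <- min(segment, n)
  step <- max(1L, segment %/% 2L)
  starts <- seq(1L, n - segment + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))
  acc <- numeric(segment)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / (length(starts) * sum(w^2) * fs)
  half <- seq_len(segment %/% 2L + 1L)
  tibble::tibble(freq = (half - 1) * fs / segment, power = acc[half])
}

#' Frequency of the dominant spectral peak
#'
#' @inheritParams welch_psd
#' @return Peak frequency in Hz.
#' @export
spectral_peak <- function(x, fs, segment = 4096) {
  psd <- welch_psd(x, fs, segment)
  psd$freq[which.max(psd$power)]
}
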