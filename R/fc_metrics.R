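#' FFT band-pass filter
#'
#' Zeroes every discrete-Fourier bin whose (folded) frequency lies outside
#' `[low, high]` and inverse-transforms; Hermitian symmetry is preserved by
#' filtering on the folded frequency axis, so the output is real and has the
#' same length as the input.
#'
#' @param x Finite numeric series, length >= 2.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs Sample rate (Hz).
#' @return Filtered series, same length as `x`.
#' @examples
#' fs <- 250; t <- seq(0, 2 - 1/fs, by = 1/fs)
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t)
#' y <- bandpass_fft(x, 8, 13, fs)  # keeps the 10 Hz tone only
#' @export
bandpass_fft <- function(x, low = 8, high = 13, fs) {
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  if (anyNA(x) || any(!is.finite(x))) stop("series must be finite")
  if (low <= 0 || high >= fs / 2 || low >= high)
    stop("band must satisfy 0 < low < high < fs/2")
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # folded (two-sided) frequency
  X <- stats::fft(x)
  X[f < low | f > high] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic signal of a (band-limited) real series:
#' modulus = amplitude envelope, argument = instantaneous phase. Constructed
#' in the frequency domain by doubling positive-frequency bins and zeroing
#' negative ones.
#'
#' @param x Real numeric series.
#' @return Complex series, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Pairwise orthogonalization against signal leakage
#'
#' Removes from `y` its zero-lag linear projection on `x`:
#' `y_orth = y - (<y, x> / <x, x>) * x`, so `<y_orth, x> = 0` to floating
#' point. Used to suppress spurious zero-lag correlations produced by signal
#' leakage before computing leakage-sensitive metrics (AEC, PLV).
#'
#' @param x,y Equal-length band-passed real series; `x` must not be all zero.
#' @return `y_orth`, orthogonal to `x`.
#' @export
orthogonalize_pair <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  xx <- sum(x * x)
  if (xx == 0) stop("degenerate input: x is identically zero")
  y - (sum(y * x) / xx) * x
}

# Band-pass and analytic signal in a single spectral pass: masking the
# (Hermitian) spectrum and applying the analytic multiplier commute, so this
# equals analytic_signal(bandpass_fft(x)) to floating point while halving
# the FFT work. Re() of the result is the band-passed series itself.
.analytic_band <- function(x, low, high, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[f < low | f > high] <- 0 + 0i
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Shared scalar-metric kernels on analytic signals. `ax`, `ay` are complex
# analytic series of band-passed inputs.
.aec_analytic <- function(ax, ay) {
  ex <- Mod(ax); ey <- Mod(ay)
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0) {
    warning("constant envelope: AEC undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(ex, ey)
}
.pli_analytic <- function(ax, ay) {
  abs(mean(sign(Im(ax * Conj(ay)))))
}
.plv_analytic <- function(ax, ay) {
  z <- ax * Conj(ay)
  m <- Mod(z)
  ok <- m > 0
  if (!any(ok)) return(0)
  Mod(mean(z[ok] / m[ok]))
}

# Orthogonalize-and-evaluate in both directions, averaging the metric.
# Exploits linearity of the Hilbert transform: analytic(y - b x) = ay - b ax.
.symmetrized_orth <- function(x, y, ax, ay, kernel) {
  xx <- sum(x * x); yy <- sum(y * y)
  if (xx == 0 || yy == 0) stop("degenerate input: zero series")
  ay_o <- ay - (sum(y * x) / xx) * ax
  ax_o <- ax - (sum(x * y) / yy) * ay
  rel <- sqrt(.Machine$double.eps)
  if (sqrt(mean(Mod(ay_o)^2)) < rel * sqrt(mean(Mod(ay)^2)) ||
      sqrt(mean(Mod(ax_o)^2)) < rel * sqrt(mean(Mod(ax)^2))) {
    warning("collinear pair: orthogonalized residual is ~0, returning 0")
    return(0)
  }
  (kernel(ax, ay_o) + kernel(ay, ax_o)) / 2
}

#' Amplitude envelope correlation
#'
#' Pearson correlation between the Hilbert amplitude envelopes of two
#' band-passed series (sign retained). With `leakage_correct = TRUE` the
#' pair is orthogonalized in both directions and the two directed values are
#' averaged.
#'
#' @param x,y Band-passed real series.
#' @param leakage_correct Apply pairwise orthogonalization first?
#' @return AEC in `[-1, 1]` (`NA` with a warning for constant envelopes).
#' @export
aec <- function(x, y, leakage_correct = FALSE) {
  ax <- analytic_signal(x); ay <- analytic_signal(y)
  if (leakage_correct) .symmetrized_orth(x, y, ax, ay, .aec_analytic)
  else .aec_analytic(ax, ay)
}

#' Phase lag index
#'
#' `PLI = |mean(sign(sin(phi_x - phi_y)))|` over samples; insensitive to
#' zero-lag phase differences, hence inherently robust to signal leakage.
#'
#' @param x,y Band-passed real series.
#' @return PLI in `[0, 1]`.
#' @export
pli <- function(x, y) {
  .pli_analytic(analytic_signal(x), analytic_signal(y))
}

#' Phase locking value
#'
#' `PLV = |mean(exp(i (phi_x - phi_y)))|` over samples. Sensitive to zero-lag
#' coupling; with `leakage_correct = TRUE` the pair is orthogonalized in both
#' directions and the two values averaged.
#'
#' @inheritParams aec
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(x, y, leakage_correct = FALSE) {
  ax <- analytic_signal(x); ay <- analytic_signal(y)
  if (leakage_correct) .symmetrized_orth(x, y, ax, ay, .plv_analytic)
  else .plv_analytic(ax, ay)
}

#' Functional connectivity matrix
#'
#' Computes one of the four estimators over all region pairs of a multichannel
#' series, with the epoching scheme used throughout the package:
#'
#' * `"aec"`, `"pli"`, `"plv"`: the series is cut into `floor(S /
#'   epoch_length)` consecutive epochs; each epoch is band-pass filtered, the
#'   metric computed per epoch, and the per-epoch values arithmetic-averaged.
#' * `"aec_full"`: the concatenated whole-epoch span is filtered and the AEC
#'   computed once on the full series.
#'
#' Leakage correction (pairwise orthogonalization, both directions averaged)
#' is applied per epoch for epoched metrics and on the whole series for
#' `"aec_full"`; it is meant for (pseudo-)empirical data and for the
#' leakage-sensitive metrics only — simulated series contain no leakage, and
#' the PLI needs no correction.
#'
#' @param ts A `region_ts` (or `S x N` matrix with `fs` attribute / argument).
#' @param metric One of `"aec_full"`, `"aec"`, `"pli"`, `"plv"`.
#' @param leakage_correct Orthogonalize pairs before computing the metric?
#'   Ignored (with a warning if set) for `"pli"`.
#' @param band Pass band in Hz, default alpha `c(8, 13)`.
#' @param epoch_length Epoch length in samples (default 8192).
#' @param fs Sample rate; defaults to the `fs` attribute of `ts`.
#' @return An `fc_matrix`: symmetric `N x N` matrix (diagonal `NA`) with
#'   attributes `metric`, `leakage_corrected`, `n_epochs`, `band`.
#' @export
fc_connectivity <- function(ts, metric = c("aec_full", "aec", "pli", "plv"),
                            leakage_correct = FALSE, band = c(8, 13),
                            epoch_length = 8192, fs = attr(ts, "fs")) {
  metric <- match.arg(metric)
  x <- unclass(as.matrix(ts))
  if (is.null(fs)) stop("supply `fs` (missing attribute on `ts`)")
  S <- nrow(x); N <- ncol(x)
  n_epochs <- floor(S / epoch_length)
  if (n_epochs < 1)
    stop("series shorter than one epoch (", epoch_length, " samples)")
  if (metric == "pli" && leakage_correct) {
    warning("PLI is inherently insensitive to zero-lag leakage; ",
            "`leakage_correct` ignored")
    leakage_correct <- FALSE
  }

  kernel <- switch(metric, aec_full = .aec_analytic, aec = .aec_analytic,
                   pli = .pli_analytic, plv = .plv_analytic)

  pair_values <- function(A) {
    # A: analytic signals of the filtered (epoch or full) S' x N block
    xf <- Re(A)
    vals <- matrix(0, N, N)
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        v <- if (leakage_correct)
          .symmetrized_orth(xf[, i], xf[, j], A[, i], A[, j], kernel)
        else kernel(A[, i], A[, j])
        vals[i, j] <- vals[j, i] <- v
      }
    }
    vals
  }

  if (metric == "aec_full") {
    span <- seq_len(n_epochs * epoch_length)
    A <- apply(x[span, , drop = FALSE], 2, .analytic_band,
               low = band[1], high = band[2], fs = fs)
    vals <- pair_values(A)
  } else {
    vals <- matrix(0, N, N)
    for (e in seq_len(n_epochs)) {
      idx <- ((e - 1) * epoch_length + 1):(e * epoch_length)
      A <- apply(x[idx, , drop = FALSE], 2, .analytic_band,
                 low = band[1], high = band[2], fs = fs)
      vals <- vals + pair_values(A)
    }
    vals <- vals / n_epochs
  }
  fc_matrix(vals, metric = metric, leakage_corrected = leakage_correct,
            n_epochs = n_epochs, band = band,
            labels = colnames(x))
}

#' Functional connectivity matrix container
#'
#' @param values Symmetric `N x N` numeric matrix.
#' @param metric Metric name.
#' @param leakage_corrected Logical flag.
#' @param n_epochs Number of epochs averaged.
#' @param band Pass band (Hz).
#' @param labels Optional region labels.
#' @return An `fc_matrix`.
#' @export
fc_matrix <- function(values, metric, leakage_corrected = FALSE,
                      n_epochs = 1L, band = c(8, 13), labels = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-9)
    stop("fc matrix must be symmetric")
  diag(values) <- NA_real_
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  structure(values, metric = metric, leakage_corrected = leakage_corrected,
            n_epochs = as.integer(n_epochs), band = band,
            class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("<fc_matrix> ", attr(x, "metric"), ", ", nrow(x), " regions, ",
      attr(x, "n_epochs"), " epoch(s)",
      if (attr(x, "leakage_corrected")) ", leakage-corrected", "\n", sep = "")
  invisible(x)
}

#' Average a list of FC matrices elementwise
#'
#' @param fcs List of `fc_matrix` objects with identical metric and size.
#' @return The elementwise-mean `fc_matrix`.
#' @export
fc_average <- function(fcs) {
  stopifnot(is.list(fcs), length(fcs) >= 1)
  met <- attr(fcs[[1]], "metric")
  N <- nrow(fcs[[1]])
  for (f in fcs) {
    if (!inherits(f, "fc_matrix")) stop("all elements must be fc_matrix")
    if (!identical(attr(f, "metric"), met)) stop("mixed metrics in fc_average")
    if (nrow(f) != N) stop("mixed dimensions in fc_average")
  }
  m <- Reduce(`+`, lapply(fcs, unclass)) / length(fcs)
  fc_matrix(ifelse(is.na(m), 0, m), metric = met,
            leakage_corrected = attr(fcs[[1]], "leakage_corrected"),
            n_epochs = attr(fcs[[1]], "n_epochs"),
            band = attr(fcs[[1]], "band"), labels = rownames(fcs[[1]]))
}

#' @describeIn fc_matrix Heatmap of the connectivity matrix.
#' @param object An `fc_matrix`.
#' @param ... Unused.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  N <- nrow(object)
  labs <- rownames(object)
  if (is.null(labs)) labs <- paste0("r", seq_len(N))
  df <- expand.grid(from = factor(labs, levels = labs),
                    to = factor(labs, levels = rev(labs)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(attr(object, "metric"),
                                 if (attr(object, "leakage_corrected"))
                                   " (leakage-corrected)"),
                  x = NULL, y = NULL, fill = "FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tidy an FC matrix into an edge table
#'
#' @param x An `fc_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per region pair (`from`, `to`, `value`).
#' @export
tidy.fc_matrix <- function(x, ...) {
  N <- nrow(x)
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("r", seq_len(N))
  idx <- which(upper.tri(x), arr.ind = TRUE)
  # row-major (by row, then column) pair ordering
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(from = labs[idx[, 1]], to = labs[idx[, 2]],
                 value = unclass(x)[idx],
                 metric = attr(x, "metric"))
}
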