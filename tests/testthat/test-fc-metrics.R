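fs <- 250

test_that("FFT band-pass passes in-band tones and rejects out-of-band tones", {
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)      # integer number of cycles
  x10 <- sin(2 * pi * 10 * t)
  x30 <- sin(2 * pi * 30 * t)
  y10 <- bandpass_fft(x10, 8, 13, fs)
  expect_lt(sqrt(sum((y10 - x10)^2)) / sqrt(sum(x10^2)), 1e-6)
  y30 <- bandpass_fft(x30, 8, 13, fs)
  expect_lt(sqrt(sum(y30^2)) / sqrt(sum(x30^2)), 1e-10)
  # linearity: filtering the mixture equals filtering the in-band tone alone
  ymix <- bandpass_fft(x10 + x30, 8, 13, fs)
  expect_equal(ymix, y10, tolerance = 1e-10)
  expect_error(bandpass_fft(x10, 0, 13, fs), "band")
  expect_error(bandpass_fft(x10, 8, 200, fs), "band")
  expect_error(bandpass_fft(x10, 13, 8, fs), "band")
})

test_that("analytic signal recovers envelope and phase of narrowband signals", {
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  a <- 2.5
  x <- a * cos(2 * pi * 10 * t)
  z <- analytic_signal(x)
  interior <- seq(fs, length(t) - fs)
  expect_true(all(abs(Mod(z[interior]) - a) / a < 0.01))
  dphi <- diff(Arg(z[interior])) %% (2 * pi)
  expect_equal(median(dphi), 2 * pi * 10 / fs, tolerance = 1e-3)
  # amplitude-modulated tone: envelope matches a quadrature demodulation
  env <- 1 + 0.5 * cos(2 * pi * 0.5 * t)
  xm <- env * cos(2 * pi * 10 * t)
  zm <- analytic_signal(xm)
  # oracle: demodulate at the known carrier and low-pass by moving average
  iq <- xm * exp(-2i * pi * 10 * t)
  w <- rep(1 / 25, 25)
  env_oracle <- 2 * Mod(stats::filter(iq, w, sides = 2))
  ok <- !is.na(env_oracle)
  ok[seq_len(fs)] <- FALSE; ok[seq(length(t) - fs, length(t))] <- FALSE
  expect_lt(max(abs(Mod(zm)[ok] - env_oracle[ok])), 0.05)
})

test_that("pairwise orthogonalization removes the zero-lag projection", {
  set.seed(3)
  x <- narrowband_noise(2048, seed = 10)
  y <- narrowband_noise(2048, seed = 11)
  y_o <- orthogonalize_pair(x, y)
  expect_lt(abs(sum(y_o * x)), 1e-10 * sqrt(sum(x^2)) * sqrt(sum(y^2)))
  # already orthogonal input is returned unchanged
  expect_equal(orthogonalize_pair(x, y_o), y_o, tolerance = 1e-12)
  # collinear input maps to the zero vector
  expect_equal(orthogonalize_pair(x, 2 * x), rep(0, 2048), tolerance = 1e-10)
  expect_error(orthogonalize_pair(rep(0, 100), rnorm(100)), "zero")
  expect_error(orthogonalize_pair(rnorm(5), rnorm(6)), "length")
})

test_that("AEC is 1 for identical signals, ~0 for independent ones, high for shared envelopes", {
  x <- narrowband_noise(2^14, seed = 21)
  expect_equal(aec(x, x), 1)
  y <- narrowband_noise(2^14, seed = 22)
  expect_lt(abs(aec(x, y)), 0.1)   # long independent narrowband null
  # amplitude-comodulated pair: same slow envelope, different phase
  t <- seq_len(2^13) / fs
  env <- 1 + 0.8 * sin(2 * pi * 0.3 * t)
  a <- env * cos(2 * pi * 10 * t)
  b <- env * cos(2 * pi * 10 * t + 2)
  expect_gt(aec(a, b), 0.95)
})

test_that("PLI and PLV match their direct definitions on toy series", {
  x <- narrowband_noise(512, seed = 31)
  y <- narrowband_noise(512, seed = 32)
  phx <- Arg(analytic_signal(x))
  phy <- Arg(analytic_signal(y))
  # brute-force loops over the definitions
  s <- 0
  for (k in seq_along(phx)) s <- s + sign(sin(phx[k] - phy[k]))
  expect_equal(pli(x, y), abs(s / length(phx)), tolerance = 1e-12)
  z <- 0 + 0i
  for (k in seq_along(phx)) z <- z + exp(1i * (phx[k] - phy[k]))
  expect_equal(plv(x, y), Mod(z / length(phx)), tolerance = 1e-12)
})

test_that("phase metrics behave at constant lag and zero lag", {
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 10 * t)
  y <- cos(2 * pi * 10 * t - pi / 2)       # constant quarter-cycle lag
  expect_equal(pli(x, y), 1, tolerance = 1e-6)
  expect_equal(plv(x, y), 1, tolerance = 1e-6)
  expect_equal(pli(x, x), 0)               # sign(sin 0) = 0 at zero lag
  expect_equal(plv(x, x), 1)
  # independent phases: PLV near zero on long series
  a <- narrowband_noise(2^14, seed = 41)
  b <- narrowband_noise(2^14, seed = 42)
  expect_lt(plv(a, b), 0.15)
})

test_that("all metrics are invariant under channel-wise amplitude scaling", {
  x <- narrowband_noise(4096, seed = 51)
  y <- narrowband_noise(4096, seed = 52) + 0.3 * x
  for (f in list(function(a, b) aec(a, b),
                 function(a, b) aec(a, b, leakage_correct = TRUE),
                 function(a, b) pli(a, b),
                 function(a, b) plv(a, b))) {
    expect_equal(f(5 * x, 0.2 * y), f(x, y), tolerance = 1e-9)
  }
})

test_that("fc_connectivity agrees with pairwise scalar metrics on a toy network", {
  set.seed(6)
  n <- 1024
  raw <- matrix(rnorm(3 * n), n, 3)
  raw[, 2] <- raw[, 2] + 0.5 * raw[, 1]
  ts <- region_ts(raw, fs = fs)
  for (metric in c("aec", "pli", "plv")) {
    fc <- fc_connectivity(ts, metric, epoch_length = n, fs = fs)
    for (i in 1:2) for (j in (i + 1):3) {
      xf <- bandpass_fft(raw[, i], 8, 13, fs)
      yf <- bandpass_fft(raw[, j], 8, 13, fs)
      ref <- switch(metric, aec = aec(xf, yf), pli = pli(xf, yf),
                    plv = plv(xf, yf))
      expect_equal(fc[i, j], ref, tolerance = 1e-12)
      expect_equal(fc[j, i], fc[i, j])
    }
  }
  # with leakage correction too
  fc_lc <- fc_connectivity(ts, "plv", leakage_correct = TRUE,
                           epoch_length = n, fs = fs)
  xf <- bandpass_fft(raw[, 1], 8, 13, fs)
  yf <- bandpass_fft(raw[, 2], 8, 13, fs)
  expect_equal(fc_lc[1, 2], plv(xf, yf, leakage_correct = TRUE),
               tolerance = 1e-12)
})

test_that("epoching averages per-epoch metrics and aec_full matches one-epoch aec", {
  set.seed(7)
  n <- 800
  raw <- matrix(rnorm(2 * 2 * n), 2 * n, 2)
  ts <- region_ts(raw, fs = fs)
  fc2 <- fc_connectivity(ts, "pli", epoch_length = n, fs = fs)
  e1 <- fc_connectivity(region_ts(raw[1:n, ], fs = fs), "pli",
                        epoch_length = n, fs = fs)
  e2 <- fc_connectivity(region_ts(raw[(n + 1):(2 * n), ], fs = fs), "pli",
                        epoch_length = n, fs = fs)
  expect_equal(fc2[1, 2], (e1[1, 2] + e2[1, 2]) / 2, tolerance = 1e-12)
  expect_equal(attr(fc2, "n_epochs"), 2L)
  # single-epoch series: epoched AEC equals AEC over the full series
  one <- region_ts(raw[1:n, ], fs = fs)
  expect_equal(fc_connectivity(one, "aec", epoch_length = n, fs = fs)[1, 2],
               fc_connectivity(one, "aec_full", epoch_length = n,
                               fs = fs)[1, 2],
               tolerance = 1e-12)
  # trailing partial epochs are dropped
  fc_trim <- fc_connectivity(region_ts(raw[1:(n + 13), ], fs = fs), "pli",
                             epoch_length = n, fs = fs)
  expect_equal(fc_trim[1, 2], e1[1, 2], tolerance = 1e-12)
  expect_error(fc_connectivity(region_ts(raw[1:100, ], fs = fs), "pli",
                               epoch_length = n, fs = fs), "epoch")
  expect_warning(fc_connectivity(one, "pli", leakage_correct = TRUE,
                                 epoch_length = n, fs = fs), "PLI")
})

test_that("fc_connectivity is equivariant under region permutation", {
  set.seed(8)
  raw <- matrix(rnorm(4 * 1024), 1024, 4)
  ts <- region_ts(raw, fs = fs)
  perm <- c(4, 2, 1, 3)
  a <- fc_connectivity(ts, "plv", epoch_length = 1024, fs = fs)
  b <- fc_connectivity(region_ts(raw[, perm], fs = fs), "plv",
                       epoch_length = 1024, fs = fs)
  expect_equal(unclass(b), unclass(a)[perm, perm], ignore_attr = TRUE)
})

test_that("fc_average is the elementwise mean and validates inputs", {
  mk <- function(seed) {
    set.seed(seed)
    v <- matrix(rnorm(16), 4, 4)
    fc_matrix((v + t(v)) / 2, metric = "aec")
  }
  fcs <- lapply(1:5, mk)
  avg <- fc_average(fcs)
  # direct loop oracle
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_equal(avg[i, j], mean(sapply(fcs, function(f) f[i, j])),
                 tolerance = 1e-12)
  }
  expect_equal(unclass(fc_average(list(fcs[[1]], fcs[[1]]))),
               unclass(fcs[[1]]))
  neg <- fc_matrix(-unclass(fcs[[1]]), metric = "aec")
  zero <- fc_average(list(fcs[[1]], neg))
  expect_equal(max(abs(zero), na.rm = TRUE), 0)
  wrong <- fc_matrix(matrix(0, 4, 4), metric = "pli")
  expect_error(fc_average(list(fcs[[1]], wrong)), "mixed metrics")
})

test_that("zero-lag mixing inflates PLV and uncorrected AEC but not PLI", {
  # two independent narrowband sources plus mutual zero-lag leakage
  diffs_plv <- diffs_aec <- numeric(6)
  for (s in 1:6) {
    x <- narrowband_noise(2^13, seed = 600 + s)
    y <- narrowband_noise(2^13, seed = 700 + s)
    xm <- x + 0.5 * y
    ym <- y + 0.5 * x
    expect_lt(pli(xm, ym), 0.3)            # PLI stays near its null level
    diffs_plv[s] <- plv(xm, ym) - pli(xm, ym)
    diffs_aec[s] <- abs(aec(xm, ym)) -
      abs(aec(xm, ym, leakage_correct = TRUE))
  }
  expect_true(all(diffs_plv > 0))
  expect_gt(mean(diffs_aec), 0)
})
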