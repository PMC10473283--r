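#' Synthetic cohort specification
#'
#' Parameters of the fully synthetic study cohort: connectome geometry and
#' sparsity, heavy-tailed streamline-count law, inter-subject variability,
#' per-subject ground-truth coupling, and the pseudo-empirical observation
#' model (zero-lag leakage mixing plus sensor noise). The default is the
#' desk-scale profile (8 subjects, 20 regions); the full-scale profile of the
#' modelled study is 40 subjects and 78 regions.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_regions Number of regions, >= 4 (default 20; full scale 78).
#' @param density Target fraction of nonzero edges, in `(0, 1]`. The
#'   default (0.6) reflects the denser connectivity of coarse parcellations
#'   and, together with `weight_sdlog`, keeps the network's spectral radius
#'   as close as a 20-region, `[0, 1]`-weighted connectome can get to the
#'   full-scale (78-region) operating regime the coupling grid targets.
#' @param weight_meanlog,weight_sdlog Lognormal law of the base streamline
#'   counts (heavy-tailed; the winsorization step caps the extreme tail).
#' @param subject_jitter SD of the per-subject, per-edge multiplicative
#'   log-normal jitter around the shared base connectome; small values give
#'   the high-but-imperfect inter-subject SC correlation seen empirically.
#' @param K_true Per-subject ground-truth coupling (recycled); `NULL` draws
#'   them uniformly from the interior of the default coupling grid.
#' @param leakage_strength Zero-lag spatial mixing weight `lambda` in
#'   `M = (1 - lambda) I + lambda G(distance)`.
#' @param leakage_scale Gaussian distance scale of the mixing kernel `G`
#'   (mm; point-spread surrogate).
#' @param sensor_noise_sd Additive Gaussian measurement noise, expressed
#'   relative to each channel's standard deviation.
#' @param n_epochs Pseudo-empirical recording length in 8192-sample epochs
#'   (default 26, the modelled recording length).
#' @return A list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_subjects = 8, n_regions = 20, density = 0.6,
                              weight_meanlog = log(200), weight_sdlog = 0.4,
                              subject_jitter = 0.3, K_true = NULL,
                              leakage_strength = 0.25, leakage_scale = 20,
                              sensor_noise_sd = 0.25, n_epochs = 26) {
  stopifnot(n_subjects >= 1, n_regions >= 4,
            density > 0, density <= 1,
            subject_jitter >= 0, leakage_strength >= 0, leakage_strength <= 1,
            sensor_noise_sd >= 0, n_epochs >= 1)
  if (!is.null(K_true)) {
    g <- coupling_grid()
    interior <- range(g$values[-c(1, length(g$values))])
    if (any(K_true < interior[1] - 1e-9 | K_true > interior[2] + 1e-9))
      stop("K_true must lie in the interior of the default coupling grid")
    K_true <- rep_len(K_true, n_subjects)
  }
  structure(list(n_subjects = n_subjects, n_regions = n_regions,
                 density = density, weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog, subject_jitter = subject_jitter,
                 K_true = K_true, leakage_strength = leakage_strength,
                 leakage_scale = leakage_scale,
                 sensor_noise_sd = sensor_noise_sd, n_epochs = n_epochs),
            class = "synth_cohort_spec")
}

#' Hemisphere-like synthetic region geometry
#'
#' Samples region centroids on two mirrored ellipsoidal shells (semi-axes
#' 65 x 85 x 60 mm, lateral x anteroposterior x vertical) with radial
#' jitter, so pairwise Euclidean distances span the realistic tens-of-mm
#' range of cortical atlas centroids. Regions come in left/right mirrored
#' pairs (`L*`/`R*`, mirrored x-coordinates); an odd region count adds one
#' midline region.
#'
#' @param n_regions Number of regions, >= 2.
#' @param seed Integer seed (reproducible).
#' @param velocity Conduction velocity (m/s) for the delay matrix.
#' @return A [region_geometry()].
#' @export
synth_geometry <- function(n_regions, seed = 1, velocity = 10) {
  stopifnot(n_regions >= 2)
  set.seed(seed)
  n_pairs <- n_regions %/% 2
  odd <- n_regions %% 2 == 1
  ax <- c(65, 85, 60)
  u <- stats::runif(n_pairs, -0.95, 0.95)        # cos(polar angle)
  phi <- stats::runif(n_pairs, 0, pi)            # azimuth, right hemisphere
  rad <- stats::runif(n_pairs, 0.85, 1)
  st <- sqrt(1 - u^2)
  right <- cbind(x = ax[1] * rad * st * sin(phi) * 0.9 + 8,
                 y = ax[2] * rad * st * cos(phi),
                 z = ax[3] * rad * u)
  left <- right
  left[, "x"] <- -left[, "x"]
  coords <- rbind(left, right)
  labels <- c(paste0("L", seq_len(n_pairs)), paste0("R", seq_len(n_pairs)))
  if (odd) {
    coords <- rbind(coords, c(0, ax[2] * stats::runif(1, 0.85, 1), 0))
    labels <- c(labels, "M1")
  }
  rownames(coords) <- labels
  region_geometry(coords, velocity = velocity, labels = labels)
}

# connectivity check by breadth-first search on the positive-weight graph
graph_connected <- function(W) {
  N <- nrow(W)
  seen <- logical(N)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(W[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Synthetic cohort connectomes (raw streamline counts)
#'
#' Builds a shared base connectome with an exponential distance rule — edge
#' probability and expected count both decay with centroid distance — and
#' lognormal heavy-tailed counts, then applies per-subject multiplicative
#' lognormal jitter so subjects are strongly but imperfectly correlated.
#' Counts are symmetric nonnegative integers with zero diagonal. If the base
#' graph is disconnected it is resampled (bounded retries, with a warning).
#'
#' @param spec A [synth_cohort_spec()].
#' @param geometry A [region_geometry()] for the same number of regions.
#' @param seed Integer seed.
#' @return List of raw [connectome()]s, one per subject.
#' @export
synth_connectomes <- function(spec, geometry, seed = 1) {
  stopifnot(inherits(spec, "synth_cohort_spec"),
            inherits(geometry, "region_geometry"))
  N <- nrow(geometry$distance)
  if (N != spec$n_regions) stop("geometry does not match spec$n_regions")
  D <- geometry$distance
  up <- upper.tri(D)
  d0 <- 60                                  # mm, edge-probability decay
  dw <- 90                                  # mm, weight decay
  kern <- exp(-D[up] / d0)
  p_edge <- pmin(1, spec$density * kern / mean(kern))

  base <- NULL
  for (try in seq_len(20)) {
    set.seed(seed + (try - 1L) * 1000L)
    adj <- stats::rbinom(length(p_edge), 1, p_edge)
    counts <- stats::rlnorm(length(p_edge), spec$weight_meanlog,
                            spec$weight_sdlog) * exp(-D[up] / dw)
    w <- adj * counts
    W <- matrix(0, N, N)
    W[up] <- w
    W <- W + t(W)
    if (graph_connected(W)) { base <- W; break }
    warning("disconnected base connectome, resampling (attempt ", try, ")")
  }
  if (is.null(base)) stop("could not generate a connected base connectome")

  lapply(seq_len(spec$n_subjects), function(s) {
    jit <- exp(stats::rnorm(sum(up), 0, spec$subject_jitter))
    W <- matrix(0, N, N)
    W[up] <- round(base[up] * jit)
    W <- W + t(W)
    connectome(W, labels = geometry$labels)
  })
}

#' Pseudo-empirical recording for one subject
#'
#' Integrates the delay-coupled network at the subject's ground-truth
#' coupling `K_true` (seeds disjoint from any fitting seeds by the caller's
#' seed plan), then emulates source reconstruction: zero-lag spatial mixing
#' `M = (1 - lambda) I + lambda G`, where `G` is a row-normalized Gaussian
#' kernel of the centroid distances, plus additive Gaussian sensor noise
#' scaled to each channel's standard deviation. Returns the mixed series and
#' the four FC matrices under the empirical leakage-correction policy
#' (AEC full, AEC and PLV orthogonalized; PLI not).
#'
#' @param sc Normalized [connectome()].
#' @param geometry [region_geometry()].
#' @param params [jr_params()]; its `T` is overridden to cover
#'   `spec$n_epochs` whole epochs.
#' @param K_true Ground-truth coupling.
#' @param spec A [synth_cohort_spec()] (leakage and noise settings).
#' @param seed Integer seed.
#' @param epoch_length Epoch length in samples.
#' @param metrics Which FC estimators to compute (default all four).
#' @return A list with `series` (mixed `region_ts`), `fcs` (named list of
#'   `fc_matrix`: aec_full, aec, pli, plv) and `K_true`.
#' @export
synth_pseudo_empirical <- function(sc, geometry, params = jr_params(), K_true,
                                   spec = synth_cohort_spec(), seed = 1,
                                   epoch_length = 8192,
                                   metrics = c("aec_full", "aec", "pli",
                                               "plv")) {
  S <- spec$n_epochs * epoch_length
  params$T <- S / params$fs
  params <- validate_jr_params(params)
  ts <- jr_simulate(sc, geometry, params, K = K_true, seed = seed)

  lam <- spec$leakage_strength
  x <- unclass(ts)
  if (lam > 0) {
    G <- exp(-geometry$distance^2 / (2 * spec$leakage_scale^2))
    G <- G / rowSums(G)
    M <- (1 - lam) * diag(nrow(G)) + lam * G
    x <- x %*% t(M)
  }
  if (spec$sensor_noise_sd > 0) {
    sds <- apply(x, 2, stats::sd)
    x <- x + matrix(stats::rnorm(length(x)), nrow(x), ncol(x)) *
      rep(spec$sensor_noise_sd * sds, each = nrow(x))
  }
  mixed <- region_ts(x, fs = params$fs, K = K_true, seed = seed)

  metrics <- match.arg(metrics, several.ok = TRUE)
  fcs <- lapply(stats::setNames(metrics, metrics), function(m)
    fc_connectivity(mixed, m, leakage_correct = m != "pli",
                    epoch_length = epoch_length))
  list(series = mixed, fcs = fcs, K_true = K_true)
}

#' Generate a complete synthetic cohort
#'
#' Bundles everything the pipeline needs: geometry, raw and normalized
#' per-subject connectomes, the normalized group-average connectome,
#' per-subject ground-truth couplings, pseudo-empirical FC matrices, and a
#' ground-truth ledger. Sub-seeds are derived deterministically from `seed`
#' (geometry `seed + 1`, connectomes `seed + 2`, ground-truth draw
#' `seed + 3`, subject `i` recording `seed + 100 + i`), so regeneration from
#' the same seed is identical; fitting should use a disjoint seed range
#' (e.g. `seed + 10000` upward, as [run_study()] does).
#'
#' @param spec A [synth_cohort_spec()].
#' @param params A [jr_params()].
#' @param seed Master integer seed.
#' @param keep_series Keep the pseudo-empirical time series (memory-heavy)?
#' @param epoch_length Epoch length in samples.
#' @param metrics FC estimators to compute for the pseudo-empirical data.
#' @return A list of class `synth_cohort`: `spec`, `params`, `seed`,
#'   `geometry`, `sc_raw`, `sc_norm`, `sc_group`, `K_true`, `emp_fcs`,
#'   `ground_truth` (tibble), and optionally `series`.
#' @export
synth_cohort <- function(spec = synth_cohort_spec(), params = jr_params(),
                         seed = 1, keep_series = FALSE,
                         epoch_length = 8192,
                         metrics = c("aec_full", "aec", "pli", "plv")) {
  geometry <- synth_geometry(spec$n_regions, seed = seed + 1,
                             velocity = params$velocity)
  sc_raw <- synth_connectomes(spec, geometry, seed = seed + 2)
  sc_norm <- lapply(sc_raw, sc_normalize)
  sc_group <- sc_group_average(sc_raw)

  K_true <- spec$K_true
  if (is.null(K_true)) {
    g <- coupling_grid()
    interior <- g$values[-c(1, length(g$values))]
    set.seed(seed + 3)
    K_true <- sample(interior, spec$n_subjects, replace = TRUE)
  }

  emp <- lapply(seq_len(spec$n_subjects), function(i) {
    synth_pseudo_empirical(sc_norm[[i]], geometry, params, K_true[i],
                           spec = spec, seed = seed + 100 + i,
                           epoch_length = epoch_length, metrics = metrics)
  })

  structure(list(
    spec = spec, params = params, seed = seed, geometry = geometry,
    sc_raw = sc_raw, sc_norm = sc_norm, sc_group = sc_group,
    K_true = K_true,
    emp_fcs = lapply(emp, `[[`, "fcs"),
    series = if (keep_series) lapply(emp, `[[`, "series") else NULL,
    ground_truth = tibble::tibble(subject = seq_len(spec$n_subjects),
                                  K_true = K_true,
                                  seed = seed + 100 + seq_len(spec$n_subjects))),
    class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", x$spec$n_subjects, " subjects, ",
      x$spec$n_regions, " regions, K_true in [",
      min(x$K_true), ", ", max(x$K_true), "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a cohort directory (delimited text)
#'
#' `write_cohort()` lays the cohort out as plain text: per-subject raw SC
#' matrices (`sub-XX_sc.tsv`), centroids (`centroids.tsv`), per-subject FC
#' matrices with metadata sidecars (`sub-XX_fc_<metric>.tsv` /
#' `..._meta.tsv`), the ground-truth ledger (`ground_truth.tsv`) and a
#' cohort metadata file. `read_cohort()` loads the matrices back through the
#' standard readers.
#'
#' @param cohort A [synth_cohort()].
#' @param dir Target directory (created if needed).
#' @return `write_cohort()` the directory path, invisibly; `read_cohort()` a
#'   list with `geometry`, `sc_raw`, `emp_fcs`, `ground_truth`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_centroids(cohort$geometry, file.path(dir, "centroids.tsv"))
  n <- cohort$spec$n_subjects
  for (i in seq_len(n)) {
    tag <- sprintf("sub-%02d", i)
    write_connectome(cohort$sc_raw[[i]], file.path(dir, paste0(tag, "_sc.tsv")))
    for (m in names(cohort$emp_fcs[[i]])) {
      fc <- cohort$emp_fcs[[i]][[m]]
      fpath <- file.path(dir, paste0(tag, "_fc_", m, ".tsv"))
      mat <- unclass(fc)
      diag(mat) <- 0
      utils::write.table(format(mat, trim = TRUE, digits = 15), fpath,
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = rownames(fc))
      meta <- data.frame(
        key = c("metric", "leakage_corrected", "n_epochs", "band_low",
                "band_high"),
        value = c(m, attr(fc, "leakage_corrected"), attr(fc, "n_epochs"),
                  attr(fc, "band")[1], attr(fc, "band")[2]))
      utils::write.table(meta, file.path(dir, paste0(tag, "_fc_", m,
                                                     "_meta.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  info <- data.frame(key = c("n_subjects", "n_regions", "seed"),
                     value = c(n, cohort$spec$n_regions, cohort$seed))
  utils::write.table(info, file.path(dir, "cohort_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param velocity Conduction velocity (m/s) for the reloaded geometry.
#' @export
read_cohort <- function(dir, velocity = 10) {
  geometry <- read_centroids(file.path(dir, "centroids.tsv"),
                             velocity = velocity)
  gt <- readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                        show_col_types = FALSE)
  subs <- gt$subject
  sc_raw <- lapply(subs, function(i)
    read_connectome(file.path(dir, sprintf("sub-%02d_sc.tsv", i))))
  emp_fcs <- lapply(subs, function(i) {
    out <- list()
    for (m in c("aec_full", "aec", "pli", "plv")) {
      fpath <- file.path(dir, sprintf("sub-%02d_fc_%s.tsv", i, m))
      if (!file.exists(fpath)) next
      meta <- utils::read.table(
        file.path(dir, sprintf("sub-%02d_fc_%s_meta.tsv", i, m)),
        header = TRUE, sep = "\t")
      vals <- as.matrix(utils::read.table(fpath, header = TRUE, sep = "\t",
                                          check.names = FALSE))
      mv <- function(k) meta$value[meta$key == k]
      out[[m]] <- fc_matrix(vals, metric = mv("metric"),
                            leakage_corrected = as.logical(mv("leakage_corrected")),
                            n_epochs = as.integer(mv("n_epochs")),
                            band = as.numeric(c(mv("band_low"), mv("band_high"))),
                            labels = colnames(vals))
    }
    out
  })
  list(geometry = geometry, sc_raw = sc_raw, emp_fcs = emp_fcs,
       ground_truth = gt)
}
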