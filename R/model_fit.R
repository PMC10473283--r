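#' Coupling grid
#'
#' Ordered global-coupling values generated by index (`from + step * i`) to
#' avoid floating-point accumulation. The default grid is 0.1 to 0.292 in
#' steps of 0.012; [fit_coupling()] automatically continues it to
#' `extend_to = 0.4` when the best fit lands on the final grid point.
#'
#' @param from First coupling value.
#' @param to Last coupling value (must be `from + k * step`).
#' @param step Grid step.
#' @param extend_to Upper end of the automatic extension.
#' @return A list of class `coupling_grid` with `values`, `step`,
#'   `extend_to`.
#' @examples
#' length(coupling_grid()$values)  # 17
#' @export
coupling_grid <- function(from = 0.1, to = 0.292, step = 0.012,
                          extend_to = 0.4) {
  stopifnot(step > 0, to > from, extend_to >= to)
  n <- (to - from) / step
  if (abs(n - round(n)) > 1e-8) stop("`to` must equal `from + k * step`")
  structure(list(values = from + step * (0:round(n)), step = step,
                 from = from, to = to, extend_to = extend_to),
            class = "coupling_grid")
}

#' @export
print.coupling_grid <- function(x, ...) {
  cat("<coupling_grid> ", x$from, " to ", x$to, " step ", x$step,
     " (", length(x$values), " values; extension to ", x$extend_to, ")\n",
     sep = "")
  invisible(x)
}

# full index-generated sequence including the extension
grid_extension_values <- function(grid) {
  n_ext <- floor((grid$extend_to - grid$from) / grid$step + 1e-8)
  all_vals <- grid$from + grid$step * (0:n_ext)
  all_vals[all_vals > grid$to + 1e-12]
}

#' Row-major strict upper-triangle vectorization
#'
#' Extracts the `N(N-1)/2` strict upper-triangle entries of a (symmetric)
#' matrix in fixed row-major order (pair (1,2), (1,3), ..., (N-1,N)).
#'
#' @param m A square matrix (plain or `fc_matrix`).
#' @return Numeric vector of length `N(N-1)/2`.
#' @export
ut_vec <- function(m) {
  m <- as.matrix(m)
  t(m)[lower.tri(m)]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-tie ranks plus a two-sided p-value from the
#' large-sample t approximation. No multiple-comparison correction is applied
#' anywhere in the package.
#'
#' @param a,b Equal-length numeric vectors, length >= 3.
#' @return A list with `rho` and `p`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate input: constant vector, Spearman undefined")
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Fit the global coupling by sweeping the grid
#'
#' For each coupling value `K` on the grid, runs an ensemble of `n_runs`
#' simulations (seeds `base_seed + k * n_runs + r` for grid index `k`, run
#' `r`, both 0-based, so per-coupling ensembles are independent and
#' reproducible), computes the uncorrected FC per run, averages over runs,
#' and Spearman-correlates the strict upper triangle with the target FC. The
#' highest correlation over the grid is the best fit; ties go to the smallest
#' `K`. If the maximum falls on the final grid point, the grid is
#' automatically continued (same step) to `grid$extend_to` and the maximum
#' retaken over the full range.
#'
#' A simulation that blows up at some `K` is recorded as missing (with a
#' warning) and excluded from the argmax.
#'
#' @param sc Normalized [connectome()].
#' @param geometry [region_geometry()] (or `NULL` for zero delays).
#' @param params [jr_params()].
#' @param target_fc Target `fc_matrix` (same regions).
#' @param metric FC metric to simulate and match (defaults to the target's).
#' @param grid [coupling_grid()].
#' @param n_runs Ensemble size per coupling value (default 20).
#' @param base_seed Base seed of the seed schedule.
#' @param band,epoch_length Passed to [fc_connectivity()].
#' @param keep_fc Keep the run-averaged simulated FC at the optimum?
#' @return A `jr_fit` object: `curve` (tibble `K`, `rho`, `p`), `K_opt`,
#'   `rho_max`, `p_max`, `extended`, `metric`, and `best_fc` (if kept).
#' @export
fit_coupling <- function(sc, geometry, params = jr_params(), target_fc,
                         metric = attr(target_fc, "metric"),
                         grid = coupling_grid(), n_runs = 20, base_seed = 1,
                         band = c(8, 13), epoch_length = 8192,
                         keep_fc = TRUE) {
  simulator <- make_fc_simulator(sc, geometry, params, metric, n_runs,
                                 base_seed, band, epoch_length)
  fit_from_simulator(simulator, target_fc, metric, grid, keep_fc = keep_fc)
}

#' Memoised simulated-FC generator over a coupling grid
#'
#' Returns a function `f(K, k_index)` producing the run-averaged simulated
#' `fc_matrix` at coupling `K`, caching results by grid index so the same
#' sweep can serve several targets (e.g. group-SC fits against every
#' subject's empirical FC).
#'
#' @inheritParams fit_coupling
#' @return A memoising function `(K, k_index) -> fc_matrix`.
#' @export
make_fc_simulator <- function(sc, geometry, params = jr_params(), metric,
                              n_runs = 20, base_seed = 1, band = c(8, 13),
                              epoch_length = 8192) {
  cache <- new.env(parent = emptyenv())
  function(K, k_index) {
    key <- as.character(k_index)
    if (!is.null(cache[[key]])) return(cache[[key]])
    runs <- lapply(seq_len(n_runs) - 1L, function(r) {
      ts <- jr_simulate(sc, geometry, params, K = K,
                        seed = base_seed + k_index * n_runs + r)
      fc_connectivity(ts, metric = metric, leakage_correct = FALSE,
                      band = band, epoch_length = epoch_length)
    })
    out <- fc_average(runs)
    cache[[key]] <- out
    out
  }
}

#' Best-fit selection against a target FC given a simulator
#'
#' @param simulator A function from [make_fc_simulator()].
#' @param target_fc Target `fc_matrix`.
#' @param metric Metric label recorded in the result.
#' @param grid [coupling_grid()].
#' @param keep_fc Keep the simulated FC at the optimum?
#' @return A `jr_fit`.
#' @export
fit_from_simulator <- function(simulator, target_fc, metric,
                               grid = coupling_grid(), keep_fc = TRUE) {
  tvec <- ut_vec(target_fc)
  if (stats::sd(tvec) == 0)
    stop("degenerate target FC: constant upper triangle, Spearman undefined")

  eval_k <- function(K, k_index) {
    fc <- tryCatch(simulator(K, k_index), error = function(e) e)
    if (inherits(fc, "error")) {
      warning("coupling K = ", K, " failed (", conditionMessage(fc),
              "); recorded as missing", call. = FALSE)
      return(list(rho = NA_real_, p = NA_real_, fc = NULL))
    }
    sr <- spearman_rho(ut_vec(fc), tvec)
    list(rho = sr$rho, p = sr$p, fc = fc)
  }

  ks <- grid$values
  res <- lapply(seq_along(ks), function(i) eval_k(ks[i], i - 1L))
  rhos <- vapply(res, `[[`, numeric(1), "rho")
  if (all(is.na(rhos))) stop("every coupling value failed to simulate")

  extended <- FALSE
  best <- which.max(rhos)                 # first maximum: smallest K wins
  if (best == length(ks) && !is.na(rhos[best])) {
    ext <- grid_extension_values(grid)
    if (length(ext)) {
      extended <- TRUE
      res_ext <- lapply(seq_along(ext),
                        function(i) eval_k(ext[i], length(ks) + i - 1L))
      ks <- c(ks, ext)
      res <- c(res, res_ext)
      rhos <- vapply(res, `[[`, numeric(1), "rho")
      best <- which.max(rhos)
    }
  }

  curve <- tibble::tibble(K = ks, rho = rhos,
                          p = vapply(res, `[[`, numeric(1), "p"))
  structure(list(curve = curve, K_opt = ks[best], rho_max = rhos[best],
                 p_max = curve$p[best], extended = extended, metric = metric,
                 best_fc = if (keep_fc) res[[best]]$fc else NULL),
            class = "jr_fit")
}

#' @export
print.jr_fit <- function(x, ...) {
  cat("<jr_fit> metric ", x$metric, ": K_opt = ", x$K_opt,
      ", rho_max = ", signif(x$rho_max, 3),
      if (x$extended) " (grid extended)", "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_coupling Tidy the sweep curve (one row per coupling value).
#' @param x A `jr_fit`.
#' @param ... Unused.
#' @export
tidy.jr_fit <- function(x, ...) {
  dplyr::mutate(x$curve, metric = x$metric, optimal = .data$K == x$K_opt)
}

#' @describeIn fit_coupling One-row summary of the fit.
#' @export
glance.jr_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, K_opt = x$K_opt, rho_max = x$rho_max,
                 p_max = x$p_max, extended = x$extended,
                 n_coupling = nrow(x$curve))
}

#' @describeIn fit_coupling Plot the sweep curve with the optimum marked.
#' @param object A `jr_fit`.
#' @export
autoplot.jr_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$K, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$K_opt, linetype = 2) +
    ggplot2::labs(x = "global coupling K", y = "Spearman rho",
                  title = paste0("Coupling sweep (", object$metric, ")"),
                  subtitle = paste0("K_opt = ", object$K_opt, ", rho_max = ",
                                    signif(object$rho_max, 3))) +
    ggplot2::theme_minimal()
}
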