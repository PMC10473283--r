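#' Compare maximum correlations between FC metrics
#'
#' Two-sided paired Wilcoxon signed-rank test for every metric pair on the
#' per-subject maximum correlations, plus per-metric medians. The reported
#' `W` is the sum of ranks of positive differences (first metric minus
#' second). Exact distribution for n <= 25 paired differences, normal
#' approximation with continuity correction otherwise; pairs whose
#' differences are all zero are flagged as degenerate instead of tested.
#'
#' @param fits A data frame with columns `subject`, `metric`, `rho_max`
#'   (e.g. row-bound [glance()] results).
#' @return A tibble with one row per metric pair: `metric_a`, `metric_b`,
#'   `n`, `W`, `p`, `median_a`, `median_b`, `degenerate`.
#' @export
compare_metric_fits <- function(fits) {
  stopifnot(all(c("subject", "metric", "rho_max") %in% names(fits)))
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(fits), "subject", "metric", "rho_max"),
    names_from = "metric", values_from = "rho_max")
  metrics <- setdiff(names(wide), "subject")
  if (length(metrics) < 2) stop("need at least two metrics")
  if (nrow(wide) < 6)
    warning("fewer than 6 subjects: signed-rank test has little power")
  pairs <- utils::combn(metrics, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    d <- a - b
    degenerate <- all(d == 0)
    if (degenerate) {
      warning("all paired differences zero for ", pr[1], " vs ", pr[2])
      W <- NA_real_; p <- NA_real_
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE,
                           exact = length(d) <= 25, correct = TRUE))
      W <- unname(wt$statistic); p <- wt$p.value
    }
    tibble::tibble(metric_a = pr[1], metric_b = pr[2], n = length(d),
                   W = W, p = p,
                   median_a = stats::median(a), median_b = stats::median(b),
                   degenerate = degenerate)
  })
}

#' Friedman test on optimal couplings across metrics
#'
#' Tests whether the coupling values at the per-subject maximum correlation
#' differ between FC metrics (subjects as blocks, metrics as treatments).
#'
#' @param fits A data frame with columns `subject`, `metric`, `K_opt`.
#' @return A one-row tibble: `chisq`, `df`, `p`, `n_subjects`, `n_metrics`.
#' @export
compare_optimal_couplings <- function(fits) {
  stopifnot(all(c("subject", "metric", "K_opt") %in% names(fits)))
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(fits), "subject", "metric", "K_opt"),
    names_from = "metric", values_from = "K_opt")
  m <- as.matrix(wide[, setdiff(names(wide), "subject")])
  if (ncol(m) < 3 || nrow(m) < 3)
    stop("Friedman test needs >= 3 metrics and >= 3 subjects")
  const_rows <- apply(m, 1, function(r) length(unique(r)) == 1)
  if (any(const_rows))
    warning("constant rows (all metrics tied within a subject): ",
            "tie-heavy ranking")
  if (all(const_rows)) {
    # every block fully tied: no evidence of any difference (the tie
    # correction in stats::friedman.test degenerates to 0/0 here)
    return(tibble::tibble(chisq = 0, df = ncol(m) - 1, p = 1,
                          n_subjects = nrow(m), n_metrics = ncol(m)))
  }
  ft <- stats::friedman.test(m)
  tibble::tibble(chisq = unname(ft$statistic),
                 df = unname(ft$parameter), p = ft$p.value,
                 n_subjects = nrow(m), n_metrics = ncol(m))
}

#' Individual versus group-averaged structural input
#'
#' Pairs each subject's best fit obtained with their own connectome against
#' the best fit obtained with the group-averaged connectome (both fitted over
#' the full grid against the same empirical FC) and applies a two-sided
#' paired Wilcoxon signed-rank test per metric.
#'
#' @param fits_individual,fits_group Data frames with columns `subject`,
#'   `metric`, `rho_max`, over the same subjects and metrics.
#' @return A list with `pairs` (tibble: subject, metric, rho_individual,
#'   rho_group, diff) and `test` (tibble per metric: n, W, p, medians).
#' @export
individual_vs_group <- function(fits_individual, fits_group) {
  need <- c("subject", "metric", "rho_max")
  stopifnot(all(need %in% names(fits_individual)),
            all(need %in% names(fits_group)))
  a <- dplyr::select(tibble::as_tibble(fits_individual), dplyr::all_of(need))
  b <- dplyr::select(tibble::as_tibble(fits_group), dplyr::all_of(need))
  pairs <- dplyr::inner_join(a, b, by = c("subject", "metric"),
                             suffix = c("_individual", "_group"))
  if (nrow(pairs) != nrow(a) || nrow(pairs) != nrow(b))
    stop("subject/metric sets do not match between the two fit tables")
  pairs <- dplyr::rename(pairs, rho_individual = "rho_max_individual",
                         rho_group = "rho_max_group")
  pairs$diff <- pairs$rho_individual - pairs$rho_group
  test <- dplyr::group_by(pairs, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      W = if (all(.data$diff == 0)) NA_real_ else unname(suppressWarnings(
        stats::wilcox.test(.data$rho_individual, .data$rho_group,
                           paired = TRUE, exact = dplyr::n() <= 25,
                           correct = TRUE)$statistic)),
      p = if (all(.data$diff == 0)) NA_real_ else suppressWarnings(
        stats::wilcox.test(.data$rho_individual, .data$rho_group,
                           paired = TRUE, exact = dplyr::n() <= 25,
                           correct = TRUE)$p.value),
      median_individual = stats::median(.data$rho_individual),
      median_group = stats::median(.data$rho_group),
      degenerate = all(.data$diff == 0), .groups = "drop")
  list(pairs = pairs, test = test)
}

#' Matched versus nonmatched specificity analysis
#'
#' Correlates each subject's simulated FC (at their own optimal coupling)
#' with every subject's empirical FC, ranks the matched correlation among
#' all `n` values of its row, and calls it significant when it falls in the
#' top `1 - percentile` of the ranking — with the default 97.5% criterion
#' and cohorts of ~40, that means the matched value must be the strict
#' maximum (ties count against significance).
#'
#' @param sim_fcs List of simulated `fc_matrix` (one per subject, at that
#'   subject's optimal coupling).
#' @param emp_fcs List of empirical `fc_matrix` over the same subjects and
#'   metric.
#' @param percentile Ranking criterion (default 0.975).
#' @return A `specificity_result`: `cross_rho` (n x n matrix,
#'   `cross_rho[i, j]` = Spearman of simulated i vs empirical j; diagonal =
#'   matched correlations), `table` (tibble: subject, own_rho, median_other,
#'   rank, significant), `percentile`.
#' @export
specificity_analysis <- function(sim_fcs, emp_fcs, percentile = 0.975) {
  n <- length(sim_fcs)
  stopifnot(n >= 2, length(emp_fcs) == n, percentile > 0, percentile < 1)
  sim_v <- lapply(sim_fcs, ut_vec)
  emp_v <- lapply(emp_fcs, ut_vec)
  cross <- matrix(NA_real_, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      cross[i, j] <- spearman_rho(sim_v[[i]], emp_v[[j]])$rho
  own <- diag(cross)
  rank_own <- vapply(seq_len(n), function(i) sum(cross[i, ] >= own[i]),
                     numeric(1))
  allowed <- max(1, floor(n * (1 - percentile)))
  tab <- tibble::tibble(
    subject = seq_len(n), own_rho = own,
    median_other = vapply(seq_len(n),
                          function(i) stats::median(cross[i, -i]), numeric(1)),
    rank = as.integer(rank_own),
    significant = rank_own <= allowed)
  structure(list(cross_rho = cross, table = tab, percentile = percentile),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat("<specificity_result> ", nrow(x$table), " subjects, ",
      sum(x$table$significant), " with specifically matched FC (",
      x$percentile * 100, "% criterion)\n", sep = "")
  invisible(x)
}

#' @describeIn specificity_analysis Per-subject ranking table.
#' @param x A `specificity_result`.
#' @param ... Unused.
#' @export
tidy.specificity_result <- function(x, ...) x$table

#' @describeIn specificity_analysis One-row summary.
#' @export
glance.specificity_result <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$table),
                 n_significant = sum(x$table$significant),
                 percentile = x$percentile,
                 median_own = stats::median(x$table$own_rho),
                 median_other = stats::median(x$table$median_other))
}

#' @describeIn specificity_analysis Forest-style plot: matched value against
#'   the nonmatched distribution per subject.
#' @param object A `specificity_result`.
#' @export
autoplot.specificity_result <- function(object, ...) {
  n <- nrow(object$cross_rho)
  long <- tibble::tibble(
    subject = rep(seq_len(n), each = n),
    target = rep(seq_len(n), times = n),
    rho = as.vector(t(object$cross_rho)),
    matched = rep(seq_len(n), each = n) == rep(seq_len(n), times = n))
  ord <- order(object$table$own_rho - object$table$median_other)
  long$subject <- factor(long$subject, levels = object$table$subject[ord])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho, y = .data$subject)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !.data$matched),
                        colour = "grey60", size = 1) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$matched),
                        shape = 18, size = 3, colour = "black") +
    ggplot2::labs(x = "Spearman rho (simulated vs empirical)", y = "subject",
                  title = "Matched (diamond) vs nonmatched correlations") +
    ggplot2::theme_minimal()
}

#' Similarity over the strongest empirical connections
#'
#' Masks the edge set to the top fraction of empirical edges by weight
#' (ties broken by the fixed row-major edge ordering) and Spearman-correlates
#' simulated and empirical values over that mask. The mask is defined on the
#' empirical matrix; the criterion is therefore invariant under monotone
#' transforms of the empirical weights.
#'
#' @param sim_fc,emp_fc `fc_matrix` (or plain symmetric matrices).
#' @param fraction Fraction of edges kept, in `(0, 1]` (default 0.2).
#' @return One-row tibble: `rho`, `p`, `n_edges`, `fraction`.
#' @export
strongest_connections_match <- function(sim_fc, emp_fc, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  s <- ut_vec(sim_fc); e <- ut_vec(emp_fc)
  if (length(s) != length(e)) stop("matrices must have the same size")
  m <- ceiling(fraction * length(e))
  if (m < 3) stop("mask smaller than 3 edges; increase `fraction`")
  keep <- order(-e, seq_along(e))[seq_len(m)]
  sr <- spearman_rho(s[keep], e[keep])
  tibble::tibble(rho = sr$rho, p = sr$p, n_edges = m, fraction = fraction)
}
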