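#' Study run configuration
#'
#' Collects every knob of the end-to-end study so a run is fully described
#' by (cohort, config): metrics to fit, coupling grid, ensemble size, model
#' parameters, base seed of the fitting seed schedule (kept disjoint from
#' the cohort-generation seeds), specificity percentile and
#' strongest-connection fraction.
#'
#' @param metrics Character vector of FC metrics to fit.
#' @param grid A [coupling_grid()].
#' @param params A [jr_params()].
#' @param n_runs Ensemble size per coupling value.
#' @param base_seed Base seed for fitting simulations.
#' @param epoch_length Epoch length in samples.
#' @param band Analysis band (Hz).
#' @param percentile Specificity ranking criterion.
#' @param strongest_fraction Edge fraction for the strongest-connections
#'   analysis.
#' @param specificity_metric Metric used for specificity and
#'   strongest-connections (default `"aec"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(metrics = c("aec_full", "aec", "pli", "plv"),
                       grid = coupling_grid(), params = jr_params(),
                       n_runs = 20, base_seed = 10000, epoch_length = 8192,
                       band = c(8, 13), percentile = 0.975,
                       strongest_fraction = 0.2,
                       specificity_metric = "aec") {
  metrics <- match.arg(metrics, c("aec_full", "aec", "pli", "plv"),
                       several.ok = TRUE)
  stopifnot(inherits(grid, "coupling_grid"), inherits(params, "jr_params"),
            n_runs >= 1, specificity_metric %in% metrics)
  structure(list(metrics = metrics, grid = grid, params = params,
                 n_runs = n_runs, base_seed = base_seed,
                 epoch_length = epoch_length, band = band,
                 percentile = percentile,
                 strongest_fraction = strongest_fraction,
                 specificity_metric = specificity_metric),
            class = "run_config")
}

#' Deterministic hash of a run configuration
#'
#' MD5 of the canonical deparsed configuration; identical configurations
#' hash identically, so result tables can be keyed on it.
#'
#' @param config A [run_config()] (any plain list works).
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  txt <- deparse(lapply(x, function(el)
    if (is.list(el)) el[order(names(el))] else el), control = "all")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end individual-versus-group study
#'
#' Executes, on a synthetic (or loaded) cohort: per subject and metric a
#' coupling-grid fit against the subject's own pseudo-empirical FC using the
#' subject's own connectome; the same fit using the group-averaged
#' connectome (simulations shared across subjects via a memoised sweep);
#' the matched-versus-nonmatched specificity cross-matrix at each subject's
#' optimal coupling; the pairwise metric comparison and the Friedman test on
#' optimal couplings; and the strongest-connections analysis. Every result
#' row carries the configuration hash and the base seed, and a rerun with
#' the same cohort and configuration reproduces the outputs bit for bit.
#'
#' Fitting seeds are laid out per (subject, metric) as
#' `base_seed + ((subject - 1) * n_metrics + metric_index) * 10^5` for own-SC
#' fits and one block below `base_seed` for the shared group-SC sweep,
#' keeping all ensembles disjoint from each other and from the cohort
#' seeds.
#'
#' @param cohort A [synth_cohort()] (or compatible list from
#'   [read_cohort()] plus `sc_norm`, `sc_group`, `emp_fcs`).
#' @param config A [run_config()].
#' @return A list of class `study_result`: tibbles `fits`, `group_fits`,
#'   `metric_comparison`, `coupling_comparison`, `ivg_pairs`, `ivg_test`,
#'   `specificity` (plus the `specificity_result` object), `strongest`,
#'   `config`, `config_hash`, and per-subject fit objects in `fit_objects`.
#' @export
run_study <- function(cohort, config = run_config()) {
  hash <- config_hash(config)
  n <- length(cohort$sc_norm)
  metrics <- config$metrics
  geom <- cohort$geometry

  own_fits <- list()
  fit_objects <- list()
  for (i in seq_len(n)) {
    for (mi in seq_along(metrics)) {
      m <- metrics[mi]
      seed_block <- config$base_seed + ((i - 1) * length(metrics) + mi) * 1e5
      fit <- fit_coupling(cohort$sc_norm[[i]], geom, config$params,
                          target_fc = cohort$emp_fcs[[i]][[m]], metric = m,
                          grid = config$grid, n_runs = config$n_runs,
                          base_seed = seed_block, band = config$band,
                          epoch_length = config$epoch_length,
                          keep_fc = m == config$specificity_metric)
      own_fits[[length(own_fits) + 1]] <-
        dplyr::mutate(glance(fit), subject = i, .before = 1)
      fit_objects[[paste(i, m, sep = ".")]] <- fit
    }
  }
  fits <- dplyr::bind_rows(own_fits)

  # group-SC sweep: one memoised simulator per metric, reused for all targets
  group_fits <- list()
  for (mi in seq_along(metrics)) {
    m <- metrics[mi]
    sim <- make_fc_simulator(cohort$sc_group, geom, config$params, m,
                             n_runs = config$n_runs,
                             base_seed = config$base_seed - mi * 1e5,
                             band = config$band,
                             epoch_length = config$epoch_length)
    for (i in seq_len(n)) {
      fit <- fit_from_simulator(sim, cohort$emp_fcs[[i]][[m]], m,
                                grid = config$grid, keep_fc = FALSE)
      group_fits[[length(group_fits) + 1]] <-
        dplyr::mutate(glance(fit), subject = i, .before = 1)
    }
  }
  group_fits <- dplyr::bind_rows(group_fits)

  metric_comparison <- if (length(metrics) >= 2)
    compare_metric_fits(fits) else NULL
  coupling_comparison <- if (length(metrics) >= 3 && n >= 3)
    compare_optimal_couplings(fits) else NULL
  ivg <- individual_vs_group(fits, group_fits)

  sm <- config$specificity_metric
  sim_fcs <- lapply(seq_len(n),
                    function(i) fit_objects[[paste(i, sm, sep = ".")]]$best_fc)
  emp_fcs <- lapply(cohort$emp_fcs, `[[`, sm)
  spec_res <- specificity_analysis(sim_fcs, emp_fcs,
                                   percentile = config$percentile)

  strongest <- purrr::map_dfr(seq_len(n), function(i)
    dplyr::mutate(
      strongest_connections_match(sim_fcs[[i]], emp_fcs[[i]],
                                  fraction = config$strongest_fraction),
      subject = i, metric = sm, .before = 1))

  stamp <- function(df) {
    if (is.null(df)) return(NULL)
    dplyr::mutate(df, config_hash = hash, base_seed = config$base_seed)
  }
  structure(list(
    fits = stamp(fits), group_fits = stamp(group_fits),
    metric_comparison = stamp(metric_comparison),
    coupling_comparison = stamp(coupling_comparison),
    ivg_pairs = stamp(ivg$pairs), ivg_test = stamp(ivg$test),
    specificity = stamp(tidy(spec_res)),
    specificity_result = spec_res,
    strongest = stamp(strongest),
    fit_objects = fit_objects,
    config = config, config_hash = hash),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", length(unique(x$fits$subject)), " subjects x ",
      length(unique(x$fits$metric)), " metrics, config ",
      substr(x$config_hash, 1, 8), "...\n", sep = "")
  print(x$fits, n = 8)
  invisible(x)
}

#' Write study result tables as TSV
#'
#' Writes every tabular component of a [run_study()] result into `dir`.
#' Output is deterministic: the same result writes byte-identical files.
#'
#' @param result A `study_result`.
#' @param dir Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("fits", "group_fits", "metric_comparison", "coupling_comparison",
            "ivg_pairs", "ivg_test", "specificity", "strongest")
  for (tb in tabs) {
    if (is.null(result[[tb]])) next
    readr::write_tsv(result[[tb]], file.path(dir, paste0(tb, ".tsv")))
  }
  invisible(dir)
}
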