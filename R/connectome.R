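#' Structural connectome container
#'
#' Wraps a symmetric, nonnegative, zero-diagonal weight matrix (streamline
#' counts, or normalized weights in `[0, 1]`). Symmetry is enforced on
#' construction by averaging `W` and `t(W)`; a warning is raised when the
#' maximum asymmetry exceeds `1e-9`.
#'
#' @param weights `N x N` nonnegative numeric matrix.
#' @param labels Region labels (defaults to rownames or `r1..rN`).
#' @param normalized Logical: are the weights already rescaled to `[0, 1]`?
#' @return A list of class `connectome` with elements `weights`, `labels`,
#'   `normalized`.
#' @examples
#' m <- matrix(c(0, 3, 3, 0), 2, 2)
#' connectome(m)
#' @export
connectome <- function(weights, labels = NULL, normalized = FALSE) {
  weights <- as.matrix(weights)
  N <- nrow(weights)
  if (ncol(weights) != N) stop("weights must be square")
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be nonnegative")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-9)
    warning("asymmetry up to ", format(asym), " symmetrized by averaging")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("r", seq_len(N))
  if (length(labels) != N) stop("need one label per region")
  dimnames(weights) <- list(labels, labels)
  if (normalized && max(weights) > 1 + 1e-12)
    stop("normalized connectome must have weights <= 1")
  structure(list(weights = weights, labels = labels,
                 normalized = isTRUE(normalized)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$weights), " regions, ",
      sum(x$weights[upper.tri(x$weights)] > 0), " edges, ",
      if (x$normalized) "normalized" else "raw counts", "\n", sep = "")
  invisible(x)
}

#' Winsorize outlying weights and rescale to [0, 1]
#'
#' Caps link weights exceeding `Q3 + 1.5 * IQR` at that value, then divides
#' the matrix by its maximum so weights lie in `[0, 1]`. By default the
#' quartiles are computed over the strictly positive upper-triangle weights
#' (streamline matrices are sparse; including structural zeros would collapse
#' the third quartile), with linear interpolation (`stats::quantile` type 7).
#' Zeros stay zero and the ordering of surviving weights is preserved.
#'
#' @param sc A raw (non-normalized) [connectome()].
#' @param quantile_population Which entries define the quartiles:
#'   `"positive"` (default; strictly positive upper-triangle entries),
#'   `"upper"` (all upper-triangle entries), or `"all"` (all off-diagonal
#'   entries).
#' @return A normalized `connectome` with maximum weight 1.
#' @examples
#' m <- matrix(5, 3, 3); diag(m) <- 0
#' sc_normalize(connectome(m))$weights  # all-equal weights -> all 1
#' @export
sc_normalize <- function(sc, quantile_population = c("positive", "upper", "all")) {
  stopifnot(inherits(sc, "connectome"))
  if (sc$normalized) stop("connectome is already normalized")
  quantile_population <- match.arg(quantile_population)
  W <- sc$weights
  up <- W[upper.tri(W)]
  pop <- switch(quantile_population,
                positive = up[up > 0],
                upper = up,
                all = c(up, up))
  if (length(pop) == 0 || max(W) == 0)
    stop("degenerate connectome: no positive weights")
  q <- stats::quantile(pop, c(0.25, 0.75), names = FALSE, type = 7)
  cap <- q[2] + 1.5 * (q[2] - q[1])
  W[W > cap] <- cap
  W <- W / max(W)
  connectome(W, labels = sc$labels, normalized = TRUE)
}

#' Group-average a list of connectomes
#'
#' Elementwise arithmetic mean of the raw count matrices, followed by
#' [sc_normalize()] on the mean (outlier removal and rescaling are applied
#' after averaging, not before).
#'
#' @param scs List of at least two raw [connectome()]s over the same regions.
#' @param ... Passed to [sc_normalize()].
#' @return A normalized group-average `connectome`.
#' @export
sc_group_average <- function(scs, ...) {
  stopifnot(is.list(scs), length(scs) >= 2)
  if (!all(vapply(scs, inherits, logical(1), "connectome")))
    stop("all elements must be connectomes")
  if (any(vapply(scs, function(s) s$normalized, logical(1))))
    stop("group averaging operates on raw count matrices")
  labs <- scs[[1]]$labels
  for (s in scs[-1]) {
    if (!identical(dim(s$weights), dim(scs[[1]]$weights)) ||
        !identical(s$labels, labs))
      stop("connectomes must share dimensions and region labels")
  }
  M <- Reduce(`+`, lapply(scs, `[[`, "weights")) / length(scs)
  sc_normalize(connectome(M, labels = labs), ...)
}

#' Region geometry: centroids, distances and conduction delays
#'
#' Computes the pairwise Euclidean distance matrix (mm) from region centroid
#' coordinates and the conduction-delay matrix
#' `delay_ij = ||x_i - x_j|| / velocity` (distances converted mm -> m;
#' delays in seconds, zero diagonal).
#'
#' @param coordinates `N x 3` numeric matrix of centroid coordinates (mm).
#' @param velocity Conduction velocity (m/s), strictly positive.
#' @param labels Optional region labels.
#' @return A list of class `region_geometry` with `coordinates`, `labels`,
#'   `distance` (mm), `velocity` (m/s) and `delay` (s).
#' @examples
#' g <- region_geometry(rbind(c(0, 0, 0), c(100, 0, 0)), velocity = 10)
#' g$delay[1, 2]  # 100 mm at 10 m/s -> 0.01 s
#' @export
region_geometry <- function(coordinates, velocity = 10, labels = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must be N x 3 (mm)")
  if (anyNA(coordinates) || any(!is.finite(coordinates)))
    stop("coordinates must be finite")
  if (!is.numeric(velocity) || length(velocity) != 1 || velocity <= 0)
    stop("velocity must be a positive scalar (m/s)")
  N <- nrow(coordinates)
  if (is.null(labels)) labels <- rownames(coordinates)
  if (is.null(labels)) labels <- paste0("r", seq_len(N))
  D <- as.matrix(stats::dist(coordinates))
  dimnames(D) <- list(labels, labels)
  structure(list(coordinates = coordinates, labels = labels, distance = D,
                 velocity = velocity, delay = (D / 1000) / velocity),
            class = "region_geometry")
}

#' @export
print.region_geometry <- function(x, ...) {
  cat("<region_geometry> ", nrow(x$coordinates), " regions, distances ",
      round(min(x$distance[upper.tri(x$distance)]), 1), "-",
      round(max(x$distance), 1), " mm, velocity ", x$velocity, " m/s\n",
      sep = "")
  invisible(x)
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read / write a connectome as delimited text
#'
#' `read_connectome()` accepts whitespace- or comma-delimited `N x N`
#' matrices, with an optional header row of region labels.
#'
#' @param path File path.
#' @param normalized Whether the stored weights are normalized.
#' @return A [connectome()].
#' @examples
#' sc <- read_connectome(system.file("extdata", "synthetic_sc_6region.tsv",
#'                                   package = "jrnet"))
#' sc_normalize(sc)
#' @export
read_connectome <- function(path, normalized = FALSE) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(toks))))
  df <- utils::read.table(path, header = header, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  labels <- if (header) colnames(df) else NULL
  connectome(m, labels = labels, normalized = normalized)
}

#' @rdname read_connectome
#' @param sc A [connectome()].
#' @export
write_connectome <- function(sc, path) {
  utils::write.table(format(sc$weights, trim = TRUE, digits = 15),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = sc$labels)
  invisible(path)
}

#' Read / write region centroids (label, x, y, z in mm)
#'
#' @param path File path to a delimited text file with columns
#'   `label, x, y, z`.
#' @param velocity Conduction velocity (m/s) for the delay matrix.
#' @return A [region_geometry()].
#' @export
read_centroids <- function(path, velocity = 10) {
  df <- utils::read.table(path, header = TRUE,
                          sep = if (grepl(",", readLines(path, n = 1))) "," else "")
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) stop("centroid file needs columns label,x,y,z")
  region_geometry(as.matrix(df[, c("x", "y", "z")]), velocity = velocity,
                  labels = as.character(df$label))
}

#' @rdname read_centroids
#' @param geometry A [region_geometry()].
#' @export
write_centroids <- function(geometry, path) {
  df <- data.frame(label = geometry$labels,
                   x = geometry$coordinates[, 1],
                   y = geometry$coordinates[, 2],
                   z = geometry$coordinates[, 3])
  utils::write.table(format(df, trim = TRUE, digits = 15), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
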