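#' Embedding buildings into psychological space
#'
#' Under a linear metric, buildings with per-building feature values can be
#' embedded directly: each (standardized) feature column is multiplied by
#' the square root of its weight, so that Euclidean distances between the
#' embedded points equal the weighted-Euclidean metric exactly. Features
#' only available as pairwise dissimilarities (and any nonlinear metric) are
#' embedded by classical multidimensional scaling of the full pairwise
#' distance matrix.
#'
#' @name psych_space
NULL

#' Linear embedding
#'
#' @param features numeric matrix of per-building feature values (rows =
#'   buildings, named columns). Multi-column features (e.g. 2-D position)
#'   are supported through the `feature_of` attribute of the matrix (or the
#'   argument of the same name) mapping each column to a feature name; a
#'   column's feature supplies its weight and scale.
#' @param metric a [linear_metric()].
#' @param feature_of optional character vector mapping columns to feature
#'   names; defaults to the column names.
#' @return matrix of embedded points (rows = buildings).
#' @export
embed_linear <- function(features, metric, feature_of = NULL) {
  stopifnot(inherits(metric, "linear_metric"))
  X <- as.matrix(features)
  if (is.null(feature_of)) feature_of <- attr(features, "feature_of")
  if (is.null(feature_of)) feature_of <- colnames(X)
  if (length(feature_of) != ncol(X))
    stop("feature_of must name every column")
  missing <- setdiff(feature_of, names(metric$weights))
  if (length(missing))
    stop("no per-building values for metric feature(s): ",
         paste(setdiff(names(metric$weights), feature_of), collapse = ", "),
         "; use the nonlinear (MDS) embedding for pairwise-only features")
  w <- metric$weights[feature_of]
  s <- metric$scale[feature_of]
  P <- sweep(X, 2L, s, "/") * rep(sqrt(w), each = nrow(X))
  rownames(P) <- rownames(X)
  P
}

#' Classical-scaling embedding of a distance matrix
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param dim embedding dimension (< number of objects).
#' @return list with `points` (n x dim matrix; axes with non-positive
#'   eigenvalues are zero-padded) and `stress` (relative residual between
#'   embedded and input distances; positive when the input is not exactly
#'   Euclidean).
#' @export
embed_nonlinear <- function(D, dim) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (dim >= n) stop("embedding dimension must be below the number of objects")
  if (any(abs(diag(D)) > 1e-8) || any(D < -1e-12))
    stop("need a non-negative distance matrix with zero diagonal")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  mds <- suppressWarnings(stats::cmdscale(D, k = dim, eig = TRUE))
  P <- mds$points
  if (is.null(P) || ncol(P) < dim) {
    pad <- matrix(0, n, dim - if (is.null(P)) 0L else ncol(P))
    P <- cbind(P, pad)
  }
  rownames(P) <- rownames(D)
  emb <- as.matrix(stats::dist(P))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((emb - D)^2) / denom) else 0
  list(points = P, stress = stress, eig = mds$eig)
}

## Partition (named component indices) -> predicted map structure; clusters
## of size 1 are kept as flagged singleton clusters, not excluded.
clusters_to_structure <- function(z) {
  groups <- split(names(z), z)
  sizes <- vapply(groups, length, 1L)
  map_structure(submaps = unname(groups[sizes >= 2L]),
                excluded = character(),
                singleton_clusters = unname(groups[sizes == 1L]))
}

#' Predict the map structure of an environment
#'
#' Embeds the environment's buildings into the subject's psychological space
#' (direct weighting for a linear metric with per-building features,
#' classical scaling of the metric's distance matrix otherwise), clusters
#' them with a DP-GMM, and returns the resulting partition. Predicted
#' single-building clusters are kept and flagged (`singleton_clusters`);
#' scoring treats them as their own groups, i.e. as mistakes whenever the
#' subject grouped those buildings.
#'
#' @param table a [feature_table()] of the environment's pairwise
#'   differences.
#' @param buildings character vector of the environment's building IDs.
#' @param metric a fitted metric (`linear_metric` or `gda_metric`).
#' @param features optional per-building feature matrix (see
#'   [embed_linear()]); used only with a linear metric.
#' @param alpha1,truncation,restarts DP-GMM settings (see [fit_dpgmm()]).
#' @param mds_dim embedding dimension for the nonlinear route; defaults to
#'   `min(n - 1, number of features)`.
#' @param seed integer seed; the prediction is deterministic given the seed.
#' @return a [map_structure()] with attribute `embedding`.
#' @export
predict_structure <- function(table, buildings, metric, features = NULL,
                              alpha1 = 1.0, truncation = 10L,
                              restarts = 5L, mds_dim = NULL, seed = 1L) {
  buildings <- sort(as.character(buildings))
  if (inherits(metric, "linear_metric") && !is.null(features)) {
    pts <- embed_linear(features[buildings, , drop = FALSE], metric,
                        feature_of = attr(features, "feature_of"))
  } else {
    D <- metric_distance_matrix(metric, table, buildings)
    if (is.null(mds_dim))
      mds_dim <- min(length(buildings) - 1L, length(table$feature_names))
    pts <- embed_nonlinear(D, dim = mds_dim)$points
  }
  if (max(stats::dist(pts)) < 1e-12) {
    ## identical buildings: one sub-map containing everything
    out <- map_structure(submaps = list(buildings))
    attr(out, "embedding") <- pts
    return(out)
  }
  model <- fit_dpgmm(pts, alpha1 = alpha1, truncation = truncation,
                     seed = seed, restarts = restarts)
  out <- clusters_to_structure(assign_clusters(model, pts))
  attr(out, "embedding") <- pts
  out
}
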