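#' Pairwise feature tables
#'
#' The metric-learning and clustering machinery operates on per-pair feature
#' difference vectors: for every unordered pair of buildings, a vector of
#' non-negative differences/dissimilarities over named features (spatial
#' distance, visual dissimilarity, functional dissimilarity, phonetic and
#' morphological name dissimilarity surrogates, boundary and street counts,
#' and optional pairwise feature products).
#'
#' @param pairs two-column character matrix of building IDs (one row per
#'   unordered pair).
#' @param diffs numeric matrix, one row per pair, one named column per
#'   feature; all values finite and >= 0.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(pairs, diffs) {
  pairs <- as.matrix(pairs)
  diffs <- as.matrix(diffs)
  if (nrow(pairs) != nrow(diffs)) stop("pairs and diffs disagree in length")
  if (is.null(colnames(diffs))) stop("feature columns must be named")
  if (!all(is.finite(diffs)) || any(diffs < 0))
    stop("feature differences must be finite and non-negative")
  ## canonical unordered order, for stable lookup
  flip <- pairs[, 1L] > pairs[, 2L]
  pairs[flip, ] <- pairs[flip, c(2L, 1L)]
  rownames(diffs) <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  structure(list(pairs = pairs, diffs = diffs,
                 feature_names = colnames(diffs)),
            class = "feature_table")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Convert a similarity rating to a dissimilarity
#'
#' Subjects rate pairs on a bounded similarity scale (1 = not similar,
#' 10 = very similar); dissimilarity is the rating subtracted from the
#' scale maximum, so a self-similarity control pair rated at the maximum has
#' dissimilarity 0.
#'
#' @param rating numeric rating(s) within `[min_scale, max_scale]`.
#' @param max_scale,min_scale scale bounds (default 10 and 1).
#' @return dissimilarity value(s), `max_scale - rating`.
#' @export
to_dissimilarity <- function(rating, max_scale = 10, min_scale = 1) {
  if (any(rating < min_scale | rating > max_scale))
    stop("rating outside the similarity scale")
  max_scale - rating
}

#' Append pairwise feature products
#'
#' Interaction features are formed as the per-pair product of two existing
#' feature columns, named `"f1*f2"`; they let a learned metric capture
#' dependences between features.
#'
#' @param table a [feature_table()].
#' @param products list of 2-element character vectors naming the feature
#'   pairs to multiply.
#' @return a new `feature_table` with the product columns appended.
#' @export
make_feature_products <- function(table, products) {
  stopifnot(inherits(table, "feature_table"))
  d <- table$diffs
  for (pr in products) {
    if (!all(pr %in% colnames(d)))
      stop("unknown feature name: ", paste(setdiff(pr, colnames(d)),
                                           collapse = ", "))
    col <- d[, pr[1L]] * d[, pr[2L]]
    d <- cbind(d, col)
    colnames(d)[ncol(d)] <- paste(pr[1L], pr[2L], sep = "*")
  }
  feature_table(table$pairs, d)
}

#' Co-representation probability curve
#'
#' Pairs are sorted by their difference in one feature; the probability that
#' a pair at a given difference is co-represented (same sub-map) is estimated
#' as a centered moving average of the 0/1 same-sub-map labels, window `w`
#' wide, truncated and renormalized at the boundaries.
#'
#' @param diffs numeric vector of one feature's pairwise differences.
#' @param labels 0/1 vector, 1 = same sub-map, aligned with `diffs`.
#' @param w odd window size, `1 <= w <= length(diffs)`.
#' @return list with `diffs` (sorted), `p` (probabilities) and `order`.
#' @export
corepresentation_curve <- function(diffs, labels, w) {
  n <- length(diffs)
  if (n == 0L) stop("empty input")
  if (length(labels) != n) stop("diffs and labels disagree in length")
  if (w < 1L || w > n || w %% 2L == 0L)
    stop("w must be odd and between 1 and the number of pairs")
  o <- order(diffs)
  cs <- c(0, cumsum(labels[o]))
  half <- (w - 1L) / 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  p <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  list(diffs = diffs[o], p = p, order = o)
}

#' Correlations between feature differences and co-representation
#'
#' For each feature, computes Spearman's rank correlation between the
#' moving-average co-representation probabilities and the sorted feature
#' differences, at each requested window size, together with the
#' point-biserial correlation (Pearson correlation of the 0/1 labels with
#' the raw differences) used when too few pairs are available for the
#' moving-average estimate.
#'
#' @param table a [feature_table()].
#' @param labels named 0/1 vector over pair keys, or plain vector aligned
#'   with the table rows.
#' @param windows integer vector of odd window sizes (default c(5, 15, 31)).
#' @return data frame with columns `feature`, `window`, `spearman`,
#'   `biserial` (`NA` where a statistic is undefined, e.g. constant
#'   features).
#' @export
feature_correlations <- function(table, labels, windows = c(5L, 15L, 31L)) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$diffs)
  if (n < 3L) stop("need at least 3 pairs")
  labels <- as.numeric(labels)
  if (length(labels) != n) stop("labels must align with the feature table")
  out <- list()
  for (f in table$feature_names) {
    x <- table$diffs[, f]
    bis <- if (stats::sd(x) == 0 || stats::sd(labels) == 0) NA_real_
           else stats::cor(labels, x)
    for (w in windows) {
      sp <- NA_real_
      if (w <= n && stats::sd(x) > 0) {
        cur <- corepresentation_curve(x, labels, w)
        if (stats::sd(cur$p) > 0)
          sp <- stats::cor(cur$p, cur$diffs, method = "spearman")
      }
      out[[length(out) + 1L]] <- data.frame(
        feature = f, window = w, spearman = sp, biserial = bis)
    }
  }
  do.call(rbind, out)
}

#' Jaccard similarity of building-type sets
#'
#' Objective functional-similarity surrogate: the ratio of the size of the
#' intersection to the size of the union of the two buildings' type lists.
#'
#' @param types_a,types_b non-empty character vectors (sets of type labels).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_similarity <- function(types_a, types_b) {
  types_a <- unique(as.character(types_a))
  types_b <- unique(as.character(types_b))
  if (!length(types_a) || !length(types_b)) stop("type sets must be non-empty")
  length(intersect(types_a, types_b)) / length(union(types_a, types_b))
}

#' Reference correlation under single-feature clustering
#'
#' Estimates the co-representation correlation a feature would show if map
#' structure arose from clustering along that feature alone. Within each
#' environment, buildings are placed on a 1-D axis for the feature (their
#' per-building values when given; otherwise classical scaling of the
#' pairwise dissimilarity matrix), clustered with a Gaussian mixture model
#' whose component count matches the number of sub-maps in the subject's
#' actual structure, and pairs are relabelled by this artificial clustering
#' before recomputing the correlation.
#'
#' @param table a [feature_table()] for the feature's pairwise differences.
#' @param feature feature name to cluster by.
#' @param environments list; each element has `buildings` (character vector),
#'   `n_submaps` (components to fit) and optionally `values` (named
#'   per-building feature values).
#' @param window odd moving-average window; when the number of pairs is
#'   below the window, the point-biserial correlation is returned instead.
#' @return the correlation (Spearman of the probability curve, or biserial),
#'   with the artificial labels attached as attribute `labels`.
#' @export
single_feature_reference_correlation <- function(table, feature,
                                                 environments,
                                                 window = 15L) {
  stopifnot(inherits(table, "feature_table"))
  if (!feature %in% table$feature_names) stop("unknown feature: ", feature)
  x <- table$diffs[, feature]
  if (stats::sd(x) == 0) stop("degenerate single-value feature")

  labels <- rep(NA_real_, nrow(table$diffs))
  keys <- rownames(table$diffs)
  for (env in environments) {
    ids <- sort(env$buildings)
    if (length(ids) < 2L) stop("need at least 2 buildings per environment")
    if (!is.null(env$values)) {
      v <- env$values[ids]
    } else {
      D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
        k <- pair_key(ids[i], ids[j])
        D[i, j] <- D[j, i] <- table$diffs[k, feature]
      }
      v <- stats::cmdscale(D, k = 1L)[, 1L]
      names(v) <- ids
    }
    G <- max(1L, min(env$n_submaps, length(ids) - 1L))
    cl <- if (length(unique(v)) == 1L) rep(1L, length(ids)) else {
      fit <- Mclust(v, G = G, verbose = FALSE)
      if (is.null(fit)) stats::kmeans(v, centers = G)$cluster
      else fit$classification
    }
    names(cl) <- ids
    for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
      k <- pair_key(ids[i], ids[j])
      if (k %in% keys) labels[match(k, keys)] <- as.numeric(cl[ids[i]] == cl[ids[j]])
    }
  }
  use <- !is.na(labels)
  x <- x[use]; lab <- labels[use]
  r <- if (sum(use) < window || stats::sd(lab) == 0) {
    if (stats::sd(lab) == 0) NA_real_ else stats::cor(lab, x)
  } else {
    cur <- corepresentation_curve(x, lab, window)
    if (stats::sd(cur$p) == 0) NA_real_
    else stats::cor(cur$p, cur$diffs, method = "spearman")
  }
  attr(r, "labels") <- labels
  r
}
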