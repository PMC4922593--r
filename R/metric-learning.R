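#' Subject-specific dissimilarity metrics
#'
#' A subject's psychological space is characterized by a dissimilarity
#' function over pairwise feature differences. Three families are
#' implemented: a linear weighted-Euclidean metric fitted by derivative-free
#' global optimization against the subject's known sub-map structures; the
#' same linear form with weights read off a logistic decision hyperplane
#' (used with actively generated environments); and a nonlinear metric
#' defined as one minus the posterior co-representation probability of a
#' two-class Gaussian discriminant model (GDA).
#'
#' Feature differences are divided by their training-set standard deviation
#' before fitting, so weights are importances on comparable scales (spatial
#' distances vary orders of magnitude more than similarity ratings).
#'
#' @name metric_learning
NULL

#' Linear (weighted-Euclidean) metric
#'
#' @param weights named non-negative weight vector, one entry per feature;
#'   at least one weight must be positive.
#' @param scale named per-feature standardization constants (differences are
#'   divided by these before weighting; defaults to 1).
#' @return object of class `linear_metric`.
#' @export
linear_metric <- function(weights, scale = NULL) {
  weights <- unlist(weights)
  if (is.null(names(weights))) stop("weights must be named by feature")
  if (!all(is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  if (all(weights == 0)) stop("at least one weight must be positive")
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(weights)),
                                               names(weights))
  structure(list(weights = weights, scale = scale[names(weights)]),
            class = "linear_metric")
}

#' Weighted-Euclidean distance
#'
#' d_M(dx) = sqrt(sum_f w_f (dx_f / s_f)^2); equals the ordinary Euclidean
#' distance when all weights are 1 and the scales are 1.
#'
#' @param metric a [linear_metric()].
#' @param dx numeric vector of feature differences (named or ordered as the
#'   metric's weights), or a matrix with one row per pair.
#' @return non-negative distance(s).
#' @export
linear_distance <- function(metric, dx) {
  stopifnot(inherits(metric, "linear_metric"))
  w <- metric$weights
  if (is.matrix(dx)) {
    if (!is.null(colnames(dx))) dx <- dx[, names(w), drop = FALSE]
    if (ncol(dx) != length(w)) stop("dimension mismatch")
    z <- sweep(dx, 2L, metric$scale, "/")
    sqrt(as.numeric(z^2 %*% w))
  } else {
    if (!is.null(names(dx))) dx <- dx[names(w)]
    if (length(dx) != length(w)) stop("dimension mismatch")
    sqrt(sum(w * (dx / metric$scale)^2))
  }
}

## Full symmetric distance matrix over an environment's pairs.
metric_distance_matrix <- function(metric, table, buildings) {
  n <- length(buildings)
  D <- matrix(0, n, n, dimnames = list(buildings, buildings))
  keys <- pair_key(rep(buildings, each = n), rep(buildings, n))
  dim(keys) <- c(n, n)
  idx <- which(upper.tri(D))
  d <- metric_distance(metric, table$diffs[keys[idx], , drop = FALSE])
  D[idx] <- d
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

#' Dissimilarity under any fitted metric
#'
#' Generic dispatcher: weighted-Euclidean for `linear_metric`, one minus the
#' posterior co-representation probability for `gda_metric`.
#'
#' @param metric a fitted metric object.
#' @param dx difference vector or matrix (rows = pairs).
#' @return numeric distance(s).
#' @export
metric_distance <- function(metric, dx) {
  if (inherits(metric, "linear_metric")) linear_distance(metric, dx)
  else if (inherits(metric, "gda_metric")) gda_distance(metric, dx)
  else stop("unknown metric type")
}

## Per-feature standard deviations of the pooled training differences.
feature_scales <- function(tables) {
  diffs <- do.call(rbind, lapply(tables, function(t) t$diffs))
  s <- apply(diffs, 2L, stats::sd)
  s[!is.finite(s) | s < .Machine$double.eps^0.5] <- 1
  s
}

#' Fit a linear metric by global optimization
#'
#' Searches the weight hypercube for the weights minimizing
#' `1 - mean Rand index` between the subject's training structures and the
#' DP-GMM clustering obtained under the candidate metric (pairwise distances
#' -> classical scaling embedding -> DP-GMM). The search uses the
#' deterministic DIRECT rectangle-division strategy ([optim_direct()]); the
#' all-equal-weights point is the first evaluation, so the returned optimum
#' can never be worse than uniform weighting.
#'
#' @param structures list of training [map_structure()]s.
#' @param tables list of [feature_table()]s aligned with `structures`.
#' @param budget maximum number of objective evaluations (default 2000).
#' @param bounds length-2 numeric, weight bounds (default c(0, 1)).
#' @param alpha1,truncation DP-GMM settings used inside the objective.
#' @param seed integer seed for the clustering inside the objective (the
#'   optimizer itself is deterministic).
#' @param cluster_restarts initializations for the clustering inside the
#'   objective (fewer than the prediction default, for speed).
#' @return a [linear_metric()] with attributes `objective` (value reached)
#'   and `evaluations`.
#' @export
fit_linear_metric <- function(structures, tables, budget = 2000L,
                              bounds = c(0, 1), alpha1 = 1.0,
                              truncation = 10L, seed = 1L,
                              cluster_restarts = 3L) {
  if (length(structures) == 0L || length(structures) != length(tables))
    stop("need aligned, non-empty training structures and feature tables")
  nontrivial <- vapply(structures, function(m) length(m$submaps) > 0L, TRUE)
  if (!any(nontrivial))
    stop("all training structures are singleton-only; nothing to fit")
  feats <- tables[[1L]]$feature_names
  scl <- feature_scales(tables)

  objective <- function(w) {
    m <- linear_metric(stats::setNames(pmax(w, 1e-9), feats), scale = scl)
    r <- vapply(seq_along(structures), function(i) {
      pred <- cluster_under_metric(m, tables[[i]],
                                   structure_buildings(structures[[i]]),
                                   alpha1 = alpha1, truncation = truncation,
                                   seed = seed, restarts = cluster_restarts)
      rand_index(pred, structures[[i]])
    }, 0)
    1 - mean(r)
  }
  opt <- optim_direct(objective, d = length(feats),
                      lower = rep(bounds[1L], length(feats)),
                      upper = rep(bounds[2L], length(feats)),
                      budget = budget)
  out <- linear_metric(stats::setNames(pmax(opt$par, 1e-9), feats),
                       scale = scl)
  attr(out, "objective") <- opt$value
  attr(out, "evaluations") <- opt$evaluations
  out
}

## Cluster one environment under a metric: distance matrix -> classical
## scaling -> DP-GMM -> predicted structure (used by the optimizer objective
## and by greedy feature selection).
cluster_under_metric <- function(metric, table, buildings, alpha1 = 1.0,
                                 truncation = 10L, seed = 1L, restarts = 5L) {
  D <- metric_distance_matrix(metric, table, buildings)
  dim <- min(length(buildings) - 1L, length(table$feature_names))
  pts <- embed_nonlinear(D, dim = dim)$points
  model <- fit_dpgmm(pts, alpha1 = alpha1, truncation = truncation,
                     seed = seed, restarts = restarts)
  clusters_to_structure(assign_clusters(model, pts))
}

#' Fit a logistic decision hyperplane
#'
#' Maximum-likelihood logistic regression of the co-representation label on
#' the feature differences of the middle buildings, with a small L2 ridge
#' (on the slopes, not the intercept) so the estimate exists under perfect
#' separation. Differences are standardized internally; slopes are reported
#' on the standardized scale alongside the constants.
#'
#' @param dx numeric matrix of middle-building feature differences (rows =
#'   training environments).
#' @param labels 0/1 vector: 1 if the middle building was co-represented
#'   with the shop group.
#' @param ridge L2 penalty on the slopes (default 1e-4).
#' @return object of class `hyperplane_model` with `weights` (slopes,
#'   standardized scale), `intercept` and `scale`.
#' @export
fit_hyperplane <- function(dx, labels, ridge = 1e-4) {
  X <- as.matrix(dx)
  y <- as.numeric(labels)
  if (nrow(X) < 2L) stop("need at least 2 training points")
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps^0.5] <- 1
  Z <- sweep(X, 2L, scl, "/")
  d <- ncol(Z)

  negll <- function(theta) {
    eta <- Z %*% theta[seq_len(d)] + theta[d + 1L]
    -sum(y * eta - log1p(exp(eta))) + 0.5 * ridge * sum(theta[seq_len(d)]^2)
  }
  grad <- function(theta) {
    eta <- as.numeric(Z %*% theta[seq_len(d)] + theta[d + 1L])
    p <- 1 / (1 + exp(-eta))
    c(-as.numeric(crossprod(Z, y - p)) + ridge * theta[seq_len(d)],
      -sum(y - p))
  }
  fit <- stats::optim(rep(0, d + 1L), negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- fit$par[seq_len(d)]
  names(w) <- colnames(X)
  structure(list(weights = w, intercept = fit$par[d + 1L], scale = scl),
            class = "hyperplane_model")
}

#' Co-representation probability under a hyperplane model
#'
#' @param model a [fit_hyperplane()] fit.
#' @param dx difference vector or matrix (original, unstandardized scale).
#' @return probability (or vector) P(co-represented with shops | dx).
#' @export
hyperplane_probability <- function(model, dx) {
  stopifnot(inherits(model, "hyperplane_model"))
  X <- if (is.matrix(dx)) dx else matrix(dx, nrow = 1L,
                                         dimnames = list(NULL, names(dx)))
  if (!is.null(colnames(X))) X <- X[, names(model$weights), drop = FALSE]
  if (ncol(X) != length(model$weights)) stop("dimension mismatch")
  Z <- sweep(X, 2L, model$scale, "/")
  as.numeric(1 / (1 + exp(-(Z %*% model$weights + model$intercept))))
}

#' Convert a hyperplane model to a linear metric
#'
#' Feature importance is taken proportional to the magnitude of the decision
#' boundary's slope along each (standardized) feature.
#'
#' @param model a [fit_hyperplane()] fit.
#' @return a [linear_metric()] with weights `|slope|`, carrying the model's
#'   standardization constants.
#' @export
hyperplane_to_metric <- function(model) {
  stopifnot(inherits(model, "hyperplane_model"))
  linear_metric(abs(model$weights), scale = model$scale)
}

#' Propose a maximally uncertain middle building
#'
#' Uncertainty sampling for active metric learning: the least certain
#' feature-difference vectors are those with predicted probability 0.5, i.e.
#' points on the decision hyperplane. A uniform draw over the feasible box is
#' projected onto the hyperplane; draws are repeated until the projection
#' falls inside the bounds.
#'
#' @param model a [fit_hyperplane()] fit.
#' @param lower,upper numeric vectors bounding each feature difference.
#' @param seed integer seed.
#' @param max_tries attempts before concluding the hyperplane misses the box.
#' @return a feature-difference vector with `|P - 0.5| <= 0.05`.
#' @export
propose_uncertain_environment <- function(model, lower, upper, seed = 1L,
                                          max_tries = 1000L) {
  stopifnot(inherits(model, "hyperplane_model"))
  d <- length(model$weights)
  a <- model$weights / model$scale            # plane in original units
  b <- model$intercept
  if (sum(a^2) == 0) stop("degenerate hyperplane")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (i in seq_len(max_tries)) {
    x0 <- stats::runif(d, lower, upper)
    x <- x0 - as.numeric(sum(a * x0) + b) / sum(a^2) * a
    if (all(x >= lower - 1e-12) && all(x <= upper + 1e-12)) {
      x <- pmin(pmax(x, lower), upper)
      names(x) <- names(model$weights)
      p <- hyperplane_probability(model, x)
      if (abs(p - 0.5) <= 0.05) return(x)
    }
  }
  stop("decision hyperplane lies outside the feasible bounds; relax them")
}

#' Fit a Gaussian-discriminant (GDA) metric
#'
#' Models the class-conditional densities of (absolute) feature differences
#' for same-sub-map and different-sub-map pairs as multivariate Gaussians
#' with empirical priors; the metric is one minus the posterior probability
#' of co-representation. Covariances are shrunk toward their diagonal,
#' (1 - lambda) S + lambda diag(S) + eps I, for stability at small sample
#' sizes.
#'
#' @param dx matrix of pairwise feature differences (rows = pairs).
#' @param labels 0/1 vector, 1 = same sub-map.
#' @param lambda shrinkage toward the diagonal (default 0.1).
#' @param eps ridge added to the diagonal (default 1e-6).
#' @return object of class `gda_metric`.
#' @export
fit_gda_metric <- function(dx, labels, lambda = 0.1, eps = 1e-6) {
  X <- abs(as.matrix(dx))
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps^0.5] <- 1
  Z <- sweep(X, 2L, scl, "/")
  fitted_class <- function(cls) {
    Zc <- Z[y == cls, , drop = FALSE]
    mu <- colMeans(Zc)
    S <- if (nrow(Zc) > 1L) stats::cov(Zc) else diag(0, ncol(Z))
    S <- (1 - lambda) * S + lambda * diag(diag(S), ncol(Z)) +
      eps * diag(ncol(Z))
    S <- S + 1e-8 * diag(ncol(Z))  # guard exact singularity at tiny n
    if (inherits(try(chol(S), silent = TRUE), "try-error"))
      stop("covariance not positive definite after regularization")
    list(mu = mu, Sigma = S, prior = mean(y == cls))
  }
  structure(list(class0 = fitted_class(0), class1 = fitted_class(1),
                 lambda = lambda, scale = scl,
                 feature_names = colnames(X)),
            class = "gda_metric")
}

#' Posterior co-representation probability under a GDA metric
#'
#' @param metric a [fit_gda_metric()] fit.
#' @param dx difference vector or matrix.
#' @return P(same sub-map | dx) via Bayes rule over the two fitted
#'   Gaussians.
#' @export
gda_posterior <- function(metric, dx) {
  stopifnot(inherits(metric, "gda_metric"))
  X <- if (is.matrix(dx)) dx else matrix(dx, nrow = 1L,
                                         dimnames = list(NULL, names(dx)))
  if (!is.null(colnames(X)) && !is.null(metric$feature_names))
    X <- X[, metric$feature_names, drop = FALSE]
  if (ncol(X) != length(metric$scale)) stop("dimension mismatch")
  Z <- sweep(abs(X), 2L, metric$scale, "/")
  l1 <- mvn_logdensity(Z, metric$class1$mu, metric$class1$Sigma) +
    log(metric$class1$prior)
  l0 <- mvn_logdensity(Z, metric$class0$mu, metric$class0$Sigma) +
    log(metric$class0$prior)
  1 / (1 + exp(l0 - l1))
}

#' GDA dissimilarity
#'
#' d_GDA(dx) = 1 - P(same sub-map | dx), in `[0, 1]`; symmetric in pair
#' order because only absolute differences enter the fitted densities.
#'
#' @inheritParams gda_posterior
#' @return distance(s) in `[0, 1]`.
#' @export
gda_distance <- function(metric, dx) {
  1 - gda_posterior(metric, dx)
}
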