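#' Dirichlet-process Gaussian mixture clustering
#'
#' Grouping in psychological space uses a Dirichlet-process Gaussian mixture
#' model (DP-GMM): mixture weights from a truncated stick-breaking prior
#' Beta(1, alpha1), component means from N(0, I) and precisions from
#' Wishart(D, I), with the data standardized internally so those priors are
#' on the right scale. Inference is mean-field variational Bayes on the
#' truncated stick-breaking representation; components whose posterior
#' weight falls below 1/(10 * truncation) are pruned. The key property
#' inherited from the Dirichlet process is that the number of clusters is
#' inferred from the data rather than fixed in advance.
#'
#' @param points numeric matrix (rows = objects, columns = psychological-
#'   space dimensions), ideally with building IDs as row names.
#' @param alpha1 concentration of the stick-breaking prior (default 1).
#' @param truncation maximum number of mixture components (default 10).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param restarts number of deterministic initializations (Ward
#'   agglomerative cuts at 1..restarts groups); the fit with the best final
#'   variational lower bound is kept (default 5).
#' @param prior_scale overall data scale, in units of the prior's standard
#'   deviation, used when matching the data to the N(0, I) / Wishart(D, I)
#'   priors (default 3). This sets the model's resolution: the Wishart
#'   prior floors each component's covariance near W0^-1/nu, so the scale
#'   decides how tight a grouping must be, relative to the configuration's
#'   overall spread, before splitting it raises the variational bound.
#' @param beta0 coupling of the conjugate mean prior
#'   N(0, (beta0 Lambda)^-1); the small default emulates the model's
#'   independent N(0, I) mean prior (a unit-coupling conjugate prior would
#'   shrink tight clusters' means so hard that small samples never split).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   variational lower bound.
#' @return object of class `dpgmm`: mixture `weights` (posterior
#'   responsibility mass per component, so vacuous components carry none),
#'   component `means`, `covariances` (list of matrices), the
#'   standardization constants, the number of `effective` components and the
#'   variational lower bound `objective`.
#' @export
fit_dpgmm <- function(points, alpha1 = 1.0, truncation = 10L, seed = 1L,
                      restarts = 5L, beta0 = 0.01, prior_scale = 3,
                      max_iter = 200L, tol = 1e-6) {
  X <- as.matrix(points)
  n <- nrow(X)
  if (n < 2L) stop("clustering requires at least 2 points")
  D <- ncol(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  ## rotate onto the principal subspace and drop null directions, so the fit
  ## depends only on the configuration's shape, not its ambient dimension
  ## (the priors are rotation-invariant); deterministic sign convention
  sv <- svd(Xc)
  keep_dim <- which(sv$d > max(sv$d[1L], 1e-12) * 1e-8)
  if (!length(keep_dim)) keep_dim <- 1L
  V <- sv$v[, keep_dim, drop = FALSE]
  flip <- apply(V, 2L, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2L, flip, "*")
  Xp <- Xc %*% V
  ## isotropic scaling: one global scale per retained dimension, so the
  ## shape of the configuration (and with it the learned metric) is
  ## preserved while matching the N(0, I) / Wishart(D, I) priors
  s <- sqrt(mean(apply(Xp, 2L, stats::var)))
  if (!is.finite(s) || s < .Machine$double.eps^0.5) s <- 1
  s <- s / prior_scale
  Xs <- Xp / s
  D <- ncol(Xs)

  K <- as.integer(truncation)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ## deterministic initializations: Ward agglomerative cuts at 1..restarts
  ## groups, each refined by variational inference; best lower bound wins.
  hc <- stats::hclust(stats::dist(Xs), method = "ward.D2")
  best <- NULL
  for (g in seq_len(min(restarts, n, K))) {
    z <- stats::cutree(hc, k = g)
    resp <- matrix(1e-3, n, K)
    resp[cbind(seq_len(n), z)] <- 1
    resp <- resp / rowSums(resp)
    fit <- vb_dpgmm_cpp(Xs, resp, alpha1, beta0, max_iter, tol)
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }

  keep <- which(best$weights >= 1 / (10 * K))
  if (!length(keep)) keep <- which.max(best$weights)
  w <- best$weights[keep] / sum(best$weights[keep])
  means <- best$means[keep, , drop = FALSE]
  covs <- lapply(keep, function(k) {
    S <- best$covariances[, , k]
    (S + t(S)) / 2
  })

  structure(list(weights = w, means = means, covariances = covs,
                 concentration = alpha1, truncation = K,
                 effective = length(keep), objective = best$elbo,
                 center = center, scale = s, rotation = V,
                 dim = ncol(X), n = n),
            class = "dpgmm")
}

## Gaussian log-density, vectorized over rows of X.
mvn_logdensity <- function(X, mean, Sigma) {
  L <- chol(Sigma)
  xc <- sweep(X, 2L, mean)
  q <- rowSums(t(backsolve(L, t(xc), transpose = TRUE))^2)
  -0.5 * q - sum(log(diag(L))) - ncol(X) / 2 * log(2 * pi)
}

#' Hard cluster assignment under a fitted DP-GMM
#'
#' Assigns each point to the component maximizing the weighted Gaussian
#' density pi_c N(p; mu_c, Sigma_c); ties break toward the lowest component
#' index.
#'
#' @param model a fitted [fit_dpgmm()] object.
#' @param points numeric matrix of points (same columns the model was fit
#'   on, unstandardized).
#' @return integer vector of component indices, named by row names.
#' @export
assign_clusters <- function(model, points) {
  stopifnot(inherits(model, "dpgmm"))
  X <- as.matrix(points)
  if (ncol(X) != model$dim) stop("dimension mismatch")
  Xs <- (sweep(X, 2L, model$center) %*% model$rotation) / model$scale
  K <- model$effective
  ll <- vapply(seq_len(K), function(k)
    log(model$weights[k]) + mvn_logdensity(Xs, model$means[k, ],
                                           model$covariances[[k]]),
    numeric(nrow(Xs)))
  ll <- matrix(ll, nrow = nrow(Xs))
  z <- apply(ll, 1L, which.max)   # first maximum = lowest index on ties
  names(z) <- rownames(X)
  z
}
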