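#' Sketch-map validation against random chance
#'
#' Subjects draw sketch maps on an empty canvas, so only the relative
#' configuration of buildings is meaningful. Sketch and reference maps are
#' centered and scaled to unit Frobenius norm, the sketch is aligned to the
#' reference by the similarity transform (rotation with determinant +1,
#' isotropic scale, translation) minimizing the sum of squared errors, and
#' the residual SSE is compared with the SSE distribution of randomly placed
#' maps. Reflection is deliberately disallowed: a mirror-image sketch is not
#' an accurate allocentric map.
#'
#' @name map_validation
NULL

## Center and scale a coordinate matrix to unit Frobenius norm.
normalize_map <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) stop("maps need at least 3 buildings for alignment")
  if (!all(is.finite(xy))) stop("coordinates must be finite")
  xy <- sweep(xy, 2L, colMeans(xy))
  nrm <- sqrt(sum(xy^2))
  if (nrm < .Machine$double.eps^0.5)
    stop("degenerate map: all points coincident")
  xy / nrm
}

#' Reflection-free Procrustes alignment
#'
#' @param sketch,reference numeric matrices of 2-D coordinates with building
#'   IDs as row names (or plain matrices with matching row order).
#' @return list with `aligned` (the transformed sketch, in the normalized
#'   frame of the reference), `sse` (sum of squared errors after alignment),
#'   `rotation` and `scale`.
#' @rdname map_validation
#' @export
procrustes_sse <- function(sketch, reference) {
  sketch <- as.matrix(sketch); reference <- as.matrix(reference)
  if (!is.null(rownames(sketch)) && !is.null(rownames(reference))) {
    if (!setequal(rownames(sketch), rownames(reference)))
      stop("sketch and reference must contain the same building IDs")
    sketch <- sketch[rownames(reference), , drop = FALSE]
  }
  if (nrow(sketch) != nrow(reference)) stop("maps differ in size")
  X <- normalize_map(sketch)
  Y <- normalize_map(reference)
  M <- crossprod(X, Y)
  sv <- svd(M)
  d <- sv$d
  sgn <- sign(det(sv$u %*% t(sv$v)))
  if (sgn < 0) d[length(d)] <- -d[length(d)]         # forbid reflection
  Q <- sv$u %*% diag(c(rep(1, length(d) - 1L), sgn)) %*% t(sv$v)
  tr <- sum(d)
  s <- max(tr, 0)                                    # scale kept non-negative
  aligned <- s * X %*% Q
  rownames(aligned) <- rownames(reference)
  list(aligned = aligned, sse = sum((aligned - Y)^2),
       rotation = Q, scale = s)
}

#' Test a sketch map against randomly generated maps
#'
#' Generates `n_random` maps with positions uniform over the bounding box of
#' the unit-normalized reference, Procrustes-aligns each, and compares the
#' subject's SSE with the resulting null distribution. The bootstrap rule
#' accepts the sketch when its SSE beats a proportion 1 - alpha of the random
#' maps; the Z-test assumes normally distributed SSEs and accepts when the
#' one-sided z-score falls below the alpha threshold.
#'
#' @param n_random number of random maps (>= 100; 10,000 in the original
#'   analyses, where doubling it made no difference).
#' @param alpha one-sided significance level.
#' @param method `"bootstrap"` (distribution-free, preferred) or `"ztest"`.
#' @param seed integer seed for the random maps.
#' @return list with `p` (estimated probability that a random map does at
#'   least as well), `better_than_random`, `sse`, and the random `sse_null`
#'   distribution.
#' @rdname map_validation
#' @export
random_map_test <- function(sketch, reference, n_random = 10000,
                            alpha = 0.05,
                            method = c("bootstrap", "ztest"), seed = 1L) {
  method <- match.arg(method)
  if (n_random < 100L) stop("n_random must be at least 100")
  Y <- normalize_map(as.matrix(reference))
  subject <- procrustes_sse(sketch, reference)$sse

  set.seed(seed)
  n <- nrow(Y)
  lo <- apply(Y, 2L, min); hi <- apply(Y, 2L, max)
  null_sse <- vapply(seq_len(n_random), function(i) {
    R <- cbind(stats::runif(n, lo[1L], hi[1L]),
               stats::runif(n, lo[2L], hi[2L]))
    procrustes_sse(R, Y)$sse
  }, 0)

  p <- mean(null_sse <= subject)
  better <- if (method == "bootstrap") {
    p < alpha
  } else {
    z <- (subject - mean(null_sse)) / stats::sd(null_sse)
    z < stats::qnorm(alpha)
  }
  list(p = p, better_than_random = better, sse = subject,
       sse_null = null_sse, method = method, alpha = alpha)
}

#' Within- versus across-sub-map sketch distance errors
#'
#' After aligning the (unit-normalized) sketch to the reference, computes the
#' squared error between sketch and reference inter-building distances for
#' every pair of buildings belonging to sub-maps, split by whether the pair
#' shares a sub-map. Excluded singletons take part in neither group.
#'
#' @param structure a [map_structure()].
#' @return list with numeric vectors `within` and `across`; when the
#'   structure has fewer than 2 sub-maps, `across` is empty and flagged via
#'   attribute `degenerate`.
#' @rdname map_validation
#' @export
submap_sse_contrast <- function(sketch, reference, structure) {
  pr <- procrustes_sse(sketch, reference)
  A <- pr$aligned
  Y <- normalize_map(as.matrix(reference))
  if (!is.null(rownames(as.matrix(reference))))
    rownames(Y) <- rownames(as.matrix(reference))
  ids <- unlist(structure$submaps)
  if (!all(ids %in% rownames(Y)))
    stop("structure references buildings absent from the maps")
  member <- structure_membership(structure, ids)
  dA <- as.matrix(stats::dist(A[ids, , drop = FALSE]))
  dY <- as.matrix(stats::dist(Y[ids, , drop = FALSE]))
  within <- c(); across <- c()
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      err <- (dA[i, j] - dY[i, j])^2
      if (member[i] == member[j]) within <- c(within, err)
      else across <- c(across, err)
    }
  }
  out <- list(within = within, across = across)
  if (length(structure$submaps) < 2L) attr(out, "degenerate") <- TRUE
  out
}
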