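#' DIRECT (DIviding RECTangles) global optimization
#'
#' Deterministic, derivative-free Lipschitzian global minimization over a
#' box, in the classic DIRECT scheme: the search domain is normalized to the
#' unit hypercube and repeatedly trisected; at each iteration the set of
#' potentially optimal hyperrectangles (the lower-right convex hull of the
#' (size, value) scatter) is subdivided along its longest sides. The first
#' evaluation is the domain center, so with symmetric bounds the
#' uniform-weights point is always visited.
#'
#' @param fn objective function taking a numeric vector, returning a scalar.
#' @param d dimension of the search space.
#' @param lower,upper numeric bounds of length `d`.
#' @param budget maximum number of objective evaluations.
#' @param eps nonnegative balance parameter of the potential-optimality test
#'   (default 1e-4).
#' @return list with `par` (best point, original units), `value`, and
#'   `evaluations`.
#' @export
optim_direct <- function(fn, d, lower, upper, budget = 2000L, eps = 1e-4) {
  stopifnot(length(lower) == d, length(upper) == d, all(upper > lower))
  denorm <- function(u) lower + u * (upper - lower)
  evals <- 0L
  f <- function(u) { evals <<- evals + 1L; fn(denorm(u)) }

  ## rectangles: centers (matrix), side levels (matrix of trisection counts),
  ## values (vector)
  centers <- matrix(0.5, nrow = 1L, ncol = d)
  levels <- matrix(0L, nrow = 1L, ncol = d)
  values <- f(centers[1L, ])

  rect_size <- function(lv) 0.5 * sqrt(sum(3^(-2 * lv)))

  while (evals < budget) {
    sizes <- apply(levels, 1L, rect_size)
    ## best rectangle per distinct size
    ds <- sort(unique(sizes))
    cand <- vapply(ds, function(s) {
      idx <- which(sizes == s)
      idx[which.min(values[idx])]
    }, 1L)
    ## lower-right convex hull over (size, value), largest sizes kept
    hull <- integer()
    fmin <- min(values)
    for (i in seq_along(cand)) {
      j <- cand[i]
      ok <- TRUE
      for (i2 in seq_along(cand)) {
        j2 <- cand[i2]
        if (i2 == i) next
        ## j dominated if some rectangle has size >= and value <= (strictly
        ## better on one)
        if (sizes[j2] >= sizes[j] && values[j2] <= values[j] &&
            (sizes[j2] > sizes[j] || values[j2] < values[j])) { ok <- FALSE; break }
      }
      if (!ok) next
      ## Lipschitz feasibility: exists K >= 0 with value - K*size <= all
      ## candidates' value - K*size and <= fmin - eps*|fmin|
      lo <- 0
      hi <- Inf
      for (i2 in seq_along(cand)) {
        j2 <- cand[i2]
        if (j2 == j) next
        gap <- (values[j] - values[j2]) / (sizes[j] - sizes[j2] + 1e-300)
        if (sizes[j2] < sizes[j]) lo <- max(lo, gap)
        else if (sizes[j2] > sizes[j]) hi <- min(hi, gap)
      }
      if (lo > hi) next
      need <- (values[j] - (fmin - eps * max(abs(fmin), 1e-8))) /
        (sizes[j] + 1e-300)
      if (need > hi) next
      hull <- c(hull, j)
    }
    if (!length(hull)) hull <- cand[which.min(values[cand])]

    for (j in hull) {
      if (evals >= budget) break
      lv <- levels[j, ]
      long <- which(lv == min(lv))
      delta <- 3^(-(min(lv) + 1L))
      ## sample c +/- delta along each longest dimension
      trials <- list()
      for (dimn in long) {
        up <- centers[j, ]; up[dimn] <- up[dimn] + delta
        dn <- centers[j, ]; dn[dimn] <- dn[dimn] - delta
        fu <- f(up); fd <- f(dn)
        trials[[length(trials) + 1L]] <-
          list(dim = dimn, up = up, dn = dn, fu = fu, fd = fd,
               best = min(fu, fd))
        if (evals >= budget) break
      }
      if (!length(trials)) break
      ## divide dimensions in order of their best sampled value
      ord <- order(vapply(trials, function(t) t$best, 0))
      cur_lv <- lv
      for (t in trials[ord]) {
        cur_lv[t$dim] <- cur_lv[t$dim] + 1L
        centers <- rbind(centers, t$up, t$dn)
        levels <- rbind(levels, cur_lv, cur_lv)
        values <- c(values, t$fu, t$fd)
      }
      levels[j, ] <- cur_lv
    }
  }
  best <- which.min(values)
  list(par = denorm(centers[best, ]), value = values[best],
       evaluations = evals)
}
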