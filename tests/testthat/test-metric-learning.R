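test_that("weighted-Euclidean distance reduces to Euclidean at unit weights", {
  m <- linear_metric(c(f1 = 1, f2 = 1))
  expect_equal(linear_distance(m, c(f1 = 3, f2 = 4)), 5)
  expect_equal(linear_distance(m, c(f1 = 0, f2 = 0)), 0)
  m2 <- linear_metric(c(f1 = 1, f2 = 4))
  expect_equal(linear_distance(m2, c(f1 = 3, f2 = 2)), 5)
  expect_error(linear_distance(m, c(1, 2, 3)), "dimension")
})

test_that("the linear metric satisfies the metric axioms on random triples", {
  set.seed(3)
  for (i in 1:50) {
    w <- stats::setNames(stats::runif(4), paste0("f", 1:4))
    m <- linear_metric(w)
    x <- stats::rnorm(4); y <- stats::rnorm(4); z <- stats::rnorm(4)
    dxy <- linear_distance(m, stats::setNames(x - y, names(w)))
    dyx <- linear_distance(m, stats::setNames(y - x, names(w)))
    dxz <- linear_distance(m, stats::setNames(x - z, names(w)))
    dzy <- linear_distance(m, stats::setNames(z - y, names(w)))
    expect_equal(dxy, dyx)
    expect_gte(dxz + dzy + 1e-12, dxy)   # triangle inequality
    expect_gte(dxy, 0)
  }
})

test_that("DIRECT minimizes a smooth function and spends its budget deterministically", {
  f <- function(w) (w[1] - 0.32)^2 + (w[2] - 0.71)^2
  o1 <- optim_direct(f, 2, c(0, 0), c(1, 1), budget = 250)
  o2 <- optim_direct(f, 2, c(0, 0), c(1, 1), budget = 250)
  expect_identical(o1$par, o2$par)
  expect_lt(sqrt(sum((o1$par - c(0.32, 0.71))^2)), 0.02)
  ## first evaluation is the domain center
  seen <- NULL
  invisible(optim_direct(function(w) { seen <<- rbind(seen, w); sum(w^2) },
                         2, c(0, 1), c(1, 3), budget = 5))
  expect_equal(unname(seen[1, ]), c(0.5, 2))
})

test_that("optimized weights recover a subject clustering by one feature", {
  ## feature A drives the grouping, feature B is pure noise
  subj <- make_subject(91, sparsity = 5)
  w_true <- stats::setNames(c(1, 0), c("spatial", "visual"))
  set.seed(14)
  structures <- list(); tables <- list()
  for (e in 1:20) {
    env <- make_environment(700 + e, layout = "contrastive", n_active = 2)
    tab <- feature_table(env$table$pairs,
                         env$table$diffs[, c("spatial", "visual")])
    m <- linear_metric(w_true + 1e-9)
    st <- submapr:::cluster_under_metric(m, tab, env$buildings, seed = e)
    st <- map_structure(st$submaps,
                        excluded = unlist(st$singleton_clusters))
    if (length(st$submaps) == 0L) next
    structures[[length(structures) + 1L]] <- st
    tables[[length(tables) + 1L]] <- tab
  }
  fit <- fit_linear_metric(structures, tables, budget = 120, seed = 2)
  w_raw <- fit$weights / fit$scale^2
  expect_gt(w_raw["spatial"] / sum(w_raw), 0.8)
  ## optimizer is never worse than the uniform-weight start
  expect_lte(attr(fit, "objective"), 0.5)
})

test_that("an exactly separable training environment reaches objective zero", {
  env <- make_environment(41, layout = "contrastive", n_active = 5)
  m <- linear_metric(stats::setNames(rep(1, 5),
                                     colnames(env$table$diffs)))
  st <- submapr:::cluster_under_metric(m, env$table, env$buildings, seed = 1)
  st <- map_structure(st$submaps, excluded = unlist(st$singleton_clusters))
  skip_if(length(st$submaps) == 0L)
  fit <- fit_linear_metric(list(st), list(env$table), budget = 60, seed = 1)
  expect_equal(attr(fit, "objective"), 0)
})

test_that("logistic hyperplane separates 1-D classes at a sensible boundary", {
  set.seed(8)
  x <- matrix(c(stats::runif(40, 0, 1), stats::runif(40, 2, 3)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(rep(1, 40), rep(0, 40))
  h <- fit_hyperplane(x, y)
  boundary <- -h$intercept / h$weights * h$scale
  expect_gt(boundary, 1); expect_lt(boundary, 2)
  expect_lt(h$weights, 0)   # probability decreases with distance

  ## symmetric data: boundary at the midpoint
  xs <- matrix(c(stats::rnorm(5000, 0, 1), stats::rnorm(5000, 2, 1)),
               ncol = 1, dimnames = list(NULL, "f"))
  ys <- c(rep(1, 5000), rep(0, 5000))
  hs <- fit_hyperplane(xs, ys)
  expect_equal(unname(-hs$intercept / hs$weights * hs$scale), 1,
               tolerance = 0.05)
  expect_error(fit_hyperplane(x, rep(1, 80)), "both classes")
})

test_that("the ridge-free fit matches glm's maximum likelihood", {
  set.seed(9)
  X <- matrix(stats::rnorm(300), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  eta <- X %*% c(1, -2, 0.5) + 0.3
  y <- stats::rbinom(100, 1, 1 / (1 + exp(-eta)))
  h <- fit_hyperplane(X, y, ridge = 0)
  g <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(h$weights / h$scale), unname(stats::coef(g)[-1]),
               tolerance = 1e-4)
  expect_equal(unname(h$intercept), unname(stats::coef(g)[1]),
               tolerance = 1e-4)
})

test_that("uncertainty sampling proposes points on the decision hyperplane", {
  set.seed(10)
  X <- matrix(stats::runif(200, 0, 4), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- as.numeric(X[, 1] + X[, 2] < 4)
  h <- fit_hyperplane(X, y)
  for (s in 1:5) {
    p <- propose_uncertain_environment(h, lower = c(0, 0), upper = c(4, 4),
                                       seed = s)
    expect_lte(abs(hyperplane_probability(h, p) - 0.5), 0.05)
    expect_true(all(p >= 0 & p <= 4))
  }

  ## axis-aligned plane: proposals fixed along the informative axis only
  ya <- as.numeric(X[, 1] < 2)
  ha <- fit_hyperplane(X, ya)
  props <- t(vapply(1:20, function(s)
    propose_uncertain_environment(ha, c(0, 0), c(4, 4), seed = s), c(a = 0, b = 0)))
  expect_lt(stats::sd(props[, "a"]), 0.15)
  expect_gt(stats::sd(props[, "b"]), 0.5)

  ## hyperplane outside the feasible box
  yb <- as.numeric(X[, 1] + X[, 2] < 1e9)
  expect_error(fit_hyperplane(X, yb), "both classes")
})

test_that("hyperplane-derived metrics rank distances consistently with the posterior", {
  set.seed(12)
  X <- matrix(stats::runif(300, 0, 4), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(2 * X[, 1] + 0.5 * X[, 2] < 4)  # c irrelevant
  h <- fit_hyperplane(X, y)
  m <- hyperplane_to_metric(h)
  expect_gt(m$weights["a"], m$weights["c"])
  ## larger metric distance from the origin <-> lower co-representation
  d <- linear_distance(m, X)
  p <- hyperplane_probability(h, X)
  expect_lt(stats::cor(d, p, method = "spearman"), -0.6)
})

test_that("GDA posteriors match an independent Bayes computation exactly", {
  set.seed(15)
  n <- 120
  dx1 <- matrix(abs(stats::rnorm(2 * n, 0, 0.6)), ncol = 2)
  dx0 <- matrix(abs(stats::rnorm(2 * n, 2.5, 0.8)), ncol = 2)
  colnames(dx1) <- colnames(dx0) <- c("u", "v")
  g <- fit_gda_metric(rbind(dx1, dx0), c(rep(1, n), rep(0, n)))

  pts <- matrix(stats::runif(200, 0, 4), ncol = 2,
                dimnames = list(NULL, c("u", "v")))
  post <- gda_posterior(g, pts)
  for (i in 1:100) {
    z <- abs(pts[i, ]) / g$scale
    l1 <- dmvnorm_log(z, g$class1$mu, g$class1$Sigma) + log(g$class1$prior)
    l0 <- dmvnorm_log(z, g$class0$mu, g$class0$Sigma) + log(g$class0$prior)
    expect_lt(abs(post[i] - exp(l1) / (exp(l1) + exp(l0))), 1e-10)
  }
})

test_that("GDA distance is one minus the posterior with the right limits", {
  set.seed(16)
  n <- 150
  dx1 <- matrix(abs(stats::rnorm(2 * n, 0, 0.4)), ncol = 2)
  dx0 <- matrix(abs(stats::rnorm(2 * n, 3, 0.4)), ncol = 2)
  colnames(dx1) <- colnames(dx0) <- c("u", "v")
  g <- fit_gda_metric(rbind(dx1, dx0), c(rep(1, n), rep(0, n)))

  at_mu1 <- g$class1$mu * g$scale
  expect_lt(gda_distance(g, stats::setNames(at_mu1, c("u", "v"))), 0.05)

  grid <- matrix(stats::runif(400, 0, 4), ncol = 2,
                 dimnames = list(NULL, c("u", "v")))
  p <- gda_posterior(g, grid)
  expect_equal(gda_distance(g, grid), 1 - p, tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))

  ## monotone along a ray from mu1 through mu0 and beyond
  dir <- (g$class0$mu - g$class1$mu) * g$scale
  ts <- seq(1, 3, length.out = 10)
  dvals <- vapply(ts, function(t)
    gda_distance(g, stats::setNames(g$class1$mu * g$scale + t * dir,
                                    c("u", "v"))), 0)
  expect_true(all(diff(dvals) >= -1e-9))

  expect_error(fit_gda_metric(dx1, rep(1, n)), "both classes")
  expect_error(gda_distance(g, matrix(1, 1, 3)), "dimension")
})

test_that("the zero difference vector is closer than the subject median distance", {
  set.seed(17)
  n <- 100
  dx1 <- matrix(abs(stats::rnorm(2 * n, 0, 0.5)), ncol = 2)
  dx0 <- matrix(abs(stats::rnorm(2 * n, 2, 0.7)), ncol = 2)
  colnames(dx1) <- colnames(dx0) <- c("u", "v")
  g <- fit_gda_metric(rbind(dx1, dx0), c(rep(1, n), rep(0, n)))
  all_d <- gda_distance(g, rbind(dx1, dx0))
  expect_lt(gda_distance(g, c(u = 0, v = 0)), stats::median(all_d))
})

test_that("GDA captures non-monotone co-representation rules no weighted metric can", {
  ## pairs are co-represented when the visual difference is extreme (near 0
  ## or near 7) and the spatial difference small -- non-monotone in the
  ## visual axis, so any weighted-Euclidean distance must misrank part of it
  set.seed(44)
  n <- 600
  dx <- cbind(spatial = abs(stats::rnorm(n, 0, 1.2)),
              visual = sample(c(0, 3.5, 7), n, replace = TRUE) +
                stats::rnorm(n, 0, 0.2))
  lab <- as.numeric(abs(dx[, "visual"] - 3.5) > 2)
  train <- seq_len(n / 2); test <- setdiff(seq_len(n), train)
  g <- fit_gda_metric(dx[train, ], lab[train])
  post <- gda_posterior(g, dx[test, ])
  gda_acc <- mean((post > 0.5) == lab[test])

  ## best threshold on the best weighted-Euclidean distance (grid over
  ## weights and thresholds, evaluated directly on the test set -- the most
  ## favorable case for the linear metric)
  best_lin <- 0
  for (wv in seq(0, 1, length.out = 21)) {
    d <- sqrt((1 - wv) * dx[test, "spatial"]^2 + wv * dx[test, "visual"]^2)
    for (thr in stats::quantile(d, seq(0.05, 0.95, 0.05))) {
      best_lin <- max(best_lin, mean((d < thr) == lab[test]))
    }
  }
  expect_gt(gda_acc, best_lin + 0.05)
})

test_that("GDA and optimized linear pipelines score similarly when the truth is linear", {
  rg <- c(); rl <- c()
  for (si in 1:8) {
    subj <- make_subject(si * 7, sparsity = 2)
    envs <- lapply(1:5, function(e)
      make_environment(si * 300 + e, layout = "contrastive", n_active = 5))
    structs <- lapply(1:5, function(e) true_structure(subj, envs[[e]],
                                                      seed = e))
    ok <- vapply(structs, function(m) length(m$submaps) > 0, TRUE)
    if (!ok[5] || sum(ok[1:4]) < 2) next
    tr <- which(ok[1:4])
    tabs <- lapply(envs, `[[`, "table")
    td <- submapr:::training_pair_data(structs[tr], tabs[tr])
    if (length(unique(td$labels)) < 2) next
    g <- fit_gda_metric(td$dx, td$labels)
    pg <- submapr:::cluster_under_metric(g, tabs[[5]], envs[[5]]$buildings,
                                         seed = si)
    lin <- fit_linear_metric(structs[tr], tabs[tr], budget = 100, seed = si)
    pl <- submapr:::cluster_under_metric(lin, tabs[[5]], envs[[5]]$buildings,
                                         seed = si)
    rg <- c(rg, rand_index(pg, structs[[5]]))
    rl <- c(rl, rand_index(pl, structs[[5]]))
  }
  expect_gte(length(rg), 5)
  expect_lt(abs(mean(rg) - mean(rl)), 0.1)
})
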