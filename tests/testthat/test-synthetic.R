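test_that("subjects are reproducible with sparsity-controlled weights", {
  s1 <- make_subject(42)
  s2 <- make_subject(42)
  expect_identical(s1$weights, s2$weights)
  expect_equal(sum(s1$weights), 1, tolerance = 1e-12)
  expect_true(all(s1$weights >= 0))

  ## sparsity -> 0 approaches uniform weights
  flat <- make_subject(7, sparsity = 1e-4)
  expect_lt(max(abs(flat$weights - 1 / length(flat$weights))), 0.02)

  ## a sparse cohort spreads weight profiles across subjects
  cohort_w <- t(vapply(1:50, function(s) make_subject(s, sparsity = 2)$weights,
                       numeric(5)))
  expect_gt(mean(apply(cohort_w, 2, stats::sd)), 0.1)
})

test_that("the controlled training layout satisfies its invariants", {
  env <- make_environment(3, layout = "two-groups-middle")
  expect_length(env$buildings, 5L)
  g1 <- env$groups[[1]]; g2 <- env$groups[[2]]
  a <- env$attrs
  expect_equal(a[g1[1], "colour"], a[g1[2], "colour"])
  expect_equal(a[g2[1], "colour"], a[g2[2], "colour"])
  expect_equal(a[g1, "func"], c(1, 1))
  expect_equal(a[g2, "func"], c(0, 0))
  within <- c(stats::dist(env$positions[g1, ]),
              stats::dist(env$positions[g2, ]))
  between <- sqrt(sum((colMeans(env$positions[g1, ]) -
                         colMeans(env$positions[g2, ]))^2))
  expect_true(all(within < between))
  expect_identical(env$positions, make_environment(3, "two-groups-middle")$positions)
  expect_error(make_environment(1, "two-groups-middle", n_buildings = 6),
               "exactly 5")
})

test_that("random layouts scale to eight buildings with mixed functions", {
  env <- make_environment(9, layout = "random", n_buildings = 8)
  expect_length(env$buildings, 8L)
  expect_equal(nrow(env$table$pairs), choose(8, 2))
  expect_gt(length(unique(env$attrs$func)), 1L)
})

test_that("ground-truth structures are deterministic and follow proximity", {
  subj <- make_subject(5)
  env <- make_environment(11, layout = "random")
  expect_true(structures_equal(true_structure(subj, env, seed = 2),
                               true_structure(subj, env, seed = 2)))

  ## middle building placed at the shop group's centroid joins the shops
  spatial_subj <- make_subject(1)
  spatial_subj$weights <- stats::setNames(c(1, 1e-6, 1e-6, 1e-6, 1e-6),
                                          names(spatial_subj$weights))
  env2 <- make_environment(21, layout = "two-groups-middle",
                           middle = list(frac = 0.02, colour = 5, func = 1))
  st <- true_structure(spatial_subj, env2, seed = 1)
  shopmap <- st$submaps[vapply(st$submaps, function(s)
    env2$groups[[1]][1] %in% s, TRUE)]
  expect_true(env2$middle %in% unlist(shopmap))

  ## widely separated groups recovered regardless of weighting
  for (s in 1:5) {
    subj_any <- make_subject(s * 3, sparsity = 2)
    stw <- true_structure(subj_any, env2, seed = s)
    expect_gte(length(stw$submaps), 1L)
  }
})

test_that("clean recall trials list sub-maps contiguously and invert exactly", {
  st <- map_structure(list(c("A", "B"), c("C", "D", "E")))
  tr <- generate_recall_sequences(st, seed = 17)
  expect_length(tr$sequences, 7L)   # 5 cued + 2 uncued
  for (s in tr$sequences) {
    p <- match(c("A", "B"), s$ordering)
    expect_equal(abs(diff(p)), 1L)
  }
  got <- extract_structure(tr, jackknife = FALSE)
  expect_true(structures_equal(got, st))
})

test_that("swap injection corrupts exactly one sequence when forced", {
  st <- map_structure(list(c("A", "B"), c("C", "D", "E")))
  detected <- 0L
  for (s in 1:25) {
    tr <- generate_recall_sequences(st, swap_prob = 1, seed = s)
    idx <- attr(tr, "corrupted")
    expect_gt(idx, 0L)
    jk <- jackknife_outliers(tr)
    if (idx %in% jk$removed) detected <- detected + 1L
  }
  expect_gt(detected, 0L)
  expect_error(generate_recall_sequences(st, swap_prob = 2), "swap_prob")
})

test_that("sketch maps degrade gracefully with noise", {
  env <- make_environment(14, layout = "random")
  clean <- make_subject(2, sketch_sigma = 0, contraction = 1)
  sk0 <- generate_sketch_map(env, clean, seed = 4)
  expect_lt(procrustes_sse(sk0, env$positions)$sse, 1e-12)

  mean_sse <- function(sig) {
    subj <- make_subject(2, sketch_sigma = sig)
    mean(vapply(1:25, function(s)
      procrustes_sse(generate_sketch_map(env, subj, seed = s),
                     env$positions)$sse, 0))
  }
  curve <- vapply(c(0.02, 0.08, 0.25), mean_sse, 0)
  expect_true(all(diff(curve) > 0))
})

test_that("cohort generation is a pure function of configuration and seed", {
  c1 <- simulate_cohort(2, 3, seed = 5, layout = "contrastive")
  c2 <- simulate_cohort(2, 3, seed = 5, layout = "contrastive")
  expect_identical(c1[[1]]$subject$weights, c2[[1]]$subject$weights)
  expect_identical(c1[[2]]$environments[[3]]$positions,
                   c2[[2]]$environments[[3]]$positions)
  expect_true(structures_equal(c1[[1]]$structures[[2]],
                               c2[[1]]$structures[[2]]))
  expect_identical(c1[[2]]$trials[[1]]$sequences[[1]]$ordering,
                   c2[[2]]$trials[[1]]$sequences[[1]]$ordering)
})

test_that("heavily weighted features show the strongest co-representation correlations", {
  subj <- make_subject(3, sparsity = 5)
  heavy <- names(which.max(subj$weights))
  labels <- c(); diffs <- NULL
  for (e in 1:25) {
    env <- make_environment(3000 + e, layout = "contrastive", n_active = 5)
    st <- true_structure(subj, env, seed = e)
    ids <- unlist(st$submaps)
    if (length(ids) < 2) next
    mem <- submapr:::structure_membership(st, ids)
    pr <- t(utils::combn(sort(ids), 2))
    keys <- submapr:::pair_key(pr[, 1], pr[, 2])
    diffs <- rbind(diffs, env$table$diffs[keys, , drop = FALSE])
    labels <- c(labels, as.numeric(mem[pr[, 1]] == mem[pr[, 2]]))
  }
  fc <- feature_correlations(feature_table(cbind(paste0("p", seq_along(labels)),
                                                 paste0("q", seq_along(labels))),
                                           diffs),
                             labels, windows = 15L)
  r <- stats::setNames(abs(fc$biserial), fc$feature)
  expect_equal(names(which.max(r)), heavy)
})
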