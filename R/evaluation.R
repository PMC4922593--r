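#' Scoring predicted map structures
#'
#' Predictions are scored against subject structures with the Rand index
#' (fraction of building pairs on which the two partitions agree) and with
#' strict exact-match accuracy (a single misassigned building makes the
#' whole prediction incorrect). Scoring is restricted to the buildings the
#' subject actually grouped: excluded singletons in the *actual* structure
#' are dropped (they were excluded from subject data), whereas singleton
#' clusters in the *prediction* stay in as their own groups and therefore
#' count as mistakes.
#'
#' @name evaluation
NULL

#' Rand index between predicted and actual structure
#'
#' R = (s + d) / choose(B, 2), where s counts pairs on the same sub-map in
#' both partitions and d pairs on different sub-maps in both.
#'
#' @param predicted,actual [map_structure()] objects; the prediction must
#'   cover the actual structure's grouped buildings.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(predicted, actual) {
  ids <- unlist(actual$submaps)
  if (is.null(ids) || length(ids) < 2L)
    ids <- structure_buildings(actual)
  if (length(ids) < 2L) stop("need at least 2 scored buildings")
  if (!all(ids %in% structure_buildings(predicted)))
    stop("predicted and actual structures cover different building sets")
  za <- structure_membership(actual, ids)
  zp <- structure_membership(predicted, ids)
  same_a <- outer(za, za, "==")
  same_p <- outer(zp, zp, "==")
  agree <- same_a == same_p
  ut <- upper.tri(agree)
  sum(agree[ut]) / sum(ut)
}

#' Exact-match prediction accuracy
#'
#' The fraction of environments whose predicted partition matches the actual
#' one perfectly (equivalently, whose Rand index is 1).
#'
#' @param predictions,actuals aligned lists of [map_structure()]s.
#' @return fraction in `[0, 1]`.
#' @export
exact_accuracy <- function(predictions, actuals) {
  if (length(predictions) != length(actuals))
    stop("predictions and actuals differ in length")
  mean(vapply(seq_along(actuals), function(i)
    rand_index(predictions[[i]], actuals[[i]]) == 1, TRUE))
}

#' Chance probability of an exactly correct structure
#'
#' With up to K sub-maps, predicting a structure amounts to assigning one of
#' K + 1 values to each of B buildings (sub-map 1..K or own singleton), so a
#' uniformly random assignment is exactly right with probability
#' (1 / (K + 1))^B.
#'
#' @param B number of buildings (>= 1).
#' @param K maximum number of sub-maps (>= 1).
#' @return probability.
#' @export
chance_accuracy <- function(B, K) {
  stopifnot(B >= 1, K >= 1)
  (1 / (K + 1))^B
}

## Subset a feature table to named feature columns.
select_features <- function(table, features) {
  feature_table(table$pairs, table$diffs[, features, drop = FALSE])
}

## Pooled pairwise differences + same-sub-map labels over training
## environments; only pairs whose both members belong to some sub-map carry
## a label.
training_pair_data <- function(structures, tables, features = NULL) {
  dx <- NULL; y <- c()
  for (i in seq_along(structures)) {
    m <- structures[[i]]; t <- tables[[i]]
    ids <- unlist(m$submaps)
    if (length(ids) < 2L) next
    member <- structure_membership(m, ids)
    n <- length(ids)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      k <- pair_key(ids[a], ids[b])
      dx <- rbind(dx, t$diffs[k, , drop = FALSE])
      y <- c(y, as.numeric(member[a] == member[b]))
    }
  }
  if (!is.null(features) && !is.null(dx)) dx <- dx[, features, drop = FALSE]
  list(dx = dx, labels = y)
}

## Fit a metric of the requested kind on training data restricted to a
## feature subset, then predict every environment in `tables`.
fit_and_predict <- function(structures, tables, features,
                            method = c("gda", "direct"),
                            budget = 150L, shrinkage = 0.1, seed = 1L,
                            alpha1 = 1.0, truncation = 10L) {
  method <- match.arg(method)
  sub_tables <- lapply(tables, select_features, features = features)
  metric <- if (method == "gda") {
    td <- training_pair_data(structures, sub_tables)
    if (is.null(td$dx) || length(unique(td$labels)) < 2L) return(NULL)
    fit_gda_metric(td$dx, td$labels, lambda = shrinkage)
  } else {
    fit_linear_metric(structures, sub_tables, budget = budget, seed = seed,
                      alpha1 = alpha1, truncation = truncation)
  }
  preds <- lapply(seq_along(sub_tables), function(i)
    cluster_under_metric(metric, sub_tables[[i]],
                         structure_buildings(structures[[i]]),
                         alpha1 = alpha1, truncation = truncation,
                         seed = seed))
  list(metric = metric, predictions = preds)
}

#' Greedy forward feature selection
#'
#' Starting from a base feature (Euclidean distance), iteratively adds the
#' candidate feature whose inclusion maximizes the training exact accuracy
#' of the fit-and-cluster pipeline (ties broken by higher mean Rand index,
#' then input order), stopping when no candidate improves. The per-step
#' accuracies double as the ablation curve obtained by removing features
#' last-to-first.
#'
#' @param structures,tables training structures and aligned feature tables.
#' @param method metric family used in the inner fit (`"gda"` or
#'   `"direct"`).
#' @param base_feature name of the starting feature.
#' @param budget optimizer budget when `method = "direct"`.
#' @param shrinkage GDA covariance shrinkage.
#' @param seed integer seed for the clustering inside the objective.
#' @param alpha1,truncation DP-GMM settings.
#' @return list with `features` (ordered selection), `accuracy` and
#'   `mean_rand` per step, and `ablation` (accuracy when removing features
#'   last-to-first).
#' @export
greedy_feature_selection <- function(structures, tables,
                                     method = c("gda", "direct"),
                                     base_feature = "spatial",
                                     budget = 150L, shrinkage = 0.1,
                                     seed = 1L, alpha1 = 1.0,
                                     truncation = 10L) {
  method <- match.arg(method)
  all_feats <- tables[[1L]]$feature_names
  if (!base_feature %in% all_feats)
    stop("base feature not present: ", base_feature)

  score <- function(features) {
    fp <- fit_and_predict(structures, tables, features, method = method,
                          budget = budget, shrinkage = shrinkage,
                          seed = seed, alpha1 = alpha1,
                          truncation = truncation)
    if (is.null(fp)) return(c(acc = -Inf, rand = -Inf))
    r <- vapply(seq_along(structures), function(i)
      rand_index(fp$predictions[[i]], structures[[i]]), 0)
    c(acc = mean(r == 1), rand = mean(r))
  }

  selected <- base_feature
  steps <- list(score(selected))
  repeat {
    cands <- setdiff(all_feats, selected)
    if (!length(cands)) break
    sc <- lapply(cands, function(f) score(c(selected, f)))
    acc <- vapply(sc, `[[`, 0, "acc")
    rnd <- vapply(sc, `[[`, 0, "rand")
    best <- order(-acc, -rnd)[1L]   # stable: input order breaks ties
    cur <- steps[[length(steps)]]
    if (acc[best] > cur["acc"] ||
        (acc[best] == cur["acc"] && rnd[best] > cur["rand"])) {
      selected <- c(selected, cands[best])
      steps[[length(steps) + 1L]] <- sc[[best]]
    } else break
  }
  accuracy <- vapply(steps, `[[`, 0, "acc")
  list(features = selected, accuracy = accuracy,
       mean_rand = vapply(steps, `[[`, 0, "rand"),
       ablation = rev(accuracy))
}

#' Deterministic train/test split of a subject's environments
#'
#' @param env_ids identifiers of the subject's usable environments (>= 2).
#' @param n_test number of held-out test environments.
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(env_ids, n_test = 1L, seed = 1L) {
  if (length(env_ids) < 2L)
    stop("at least two environments with structure are required")
  if (n_test < 1L || n_test >= length(env_ids))
    stop("n_test must leave at least one training environment")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  test <- sort(sample(seq_along(env_ids), n_test))
  list(train = env_ids[-test], test = env_ids[test])
}

#' Undetected-distraction rate and the prediction ceiling it implies
#'
#' Repeatedly generates recall trials from the given structures, injects a
#' cross-sub-map adjacent swap into one sequence with probability
#' `swap_prob`, runs jackknife outlier removal, and records how often an
#' injected corruption both survives removal and changes the extracted
#' structure. Structures corrupted undetected put an upper bound on any
#' model's exact accuracy: the ceiling is 1 minus the probability that a
#' structure is corrupted undetected.
#'
#' @param structures list of [map_structure()]s with >= 2 groups.
#' @param swap_prob probability that a trial receives one injected swap.
#' @param n_reps number of simulated trials.
#' @param alpha jackknife significance level.
#' @param seed integer seed.
#' @param n_cued,n_uncued trial composition (defaults: one cued sequence
#'   per building plus two uncued).
#' @return list with `undetected_rate` (fraction of injected corruptions
#'   surviving with a changed structure), `detected_rate`, and `ceiling`
#'   (= 1 - swap_prob * undetected_rate).
#' @export
distraction_ceiling <- function(structures, swap_prob, n_reps = 200L,
                                alpha = 0.05, seed = 1L,
                                n_cued = NULL, n_uncued = 2L) {
  if (swap_prob < 0 || swap_prob > 1) stop("swap_prob must be in [0, 1]")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  injected <- 0L; undetected <- 0L; detected <- 0L
  for (rep in seq_len(n_reps)) {
    m <- structures[[((rep - 1L) %% length(structures)) + 1L]]
    trial <- generate_recall_sequences(m, n_cued = n_cued,
                                       n_uncued = n_uncued,
                                       swap_prob = swap_prob,
                                       seed = sample.int(2^30, 1L))
    if (!attr(trial, "corrupted")) next
    injected <- injected + 1L
    got <- extract_structure(trial, alpha = alpha)
    if (structures_equal(got, m)) detected <- detected + 1L
    else undetected <- undetected + 1L
  }
  rate <- if (injected > 0L) undetected / injected else 0
  list(undetected_rate = rate,
       detected_rate = if (injected > 0L) detected / injected else NA_real_,
       ceiling = 1 - swap_prob * rate, injected = injected)
}

#' End-to-end prediction benchmark on a synthetic cohort
#'
#' Simulates a cohort of subjects with heterogeneous feature weightings in
#' fully contrastive environments, extracts each subject's structures from
#' noise-free recall via the full tree-analysis pipeline, learns a
#' subject-specific GDA metric on the training environments, and predicts
#' the held-out test environment with DP-GMM clustering. A subject-general
#' variant pools every subject's training pairs into one shared metric, so
#' the gap between the two quantifies the value of individual psychological
#' spaces.
#'
#' @param n_subjects,n_envs cohort size (each subject holds out one test
#'   environment).
#' @param seed master seed for the cohort.
#' @param sparsity subject weight sparsity (heterogeneity across subjects).
#' @param n_active contrastive features per environment.
#' @param shrinkage GDA covariance shrinkage.
#' @return list with `specific` and `general`, each holding `exact`,
#'   `mean_rand`, `n` and the per-subject Rand indices; `NA` entries mark
#'   subjects whose test environment had no extractable structure.
#' @export
run_prediction_benchmark <- function(n_subjects = 20L, n_envs = 5L,
                                     seed = 11L, sparsity = 2,
                                     n_active = 5L, shrinkage = 0.1) {
  cohort <- simulate_cohort(n_subjects, n_envs, seed = seed,
                            layout = "contrastive", sparsity = sparsity,
                            n_active = n_active)
  res <- list(); gen_dx <- NULL; gen_y <- c()
  for (si in seq_along(cohort)) {
    s <- cohort[[si]]
    extracted <- lapply(s$trials, extract_structure)
    sp <- split_train_test(seq_len(n_envs), n_test = 1L, seed = si)
    tabs <- lapply(s$environments, `[[`, "table")
    td <- training_pair_data(extracted[sp$train], tabs[sp$train])
    gen_dx <- rbind(gen_dx, td$dx); gen_y <- c(gen_y, td$labels)
    res[[si]] <- list(td = td, test = sp$test, tabs = tabs,
                      extracted = extracted, s = s)
  }
  score <- function(metric_fn) {
    vapply(seq_along(res), function(si) {
      r <- res[[si]]
      m <- metric_fn(r)
      if (is.null(m)) return(NA_real_)
      ei <- r$test
      pred <- predict_structure(r$tabs[[ei]],
                                r$s$environments[[ei]]$buildings, m,
                                seed = si)
      act <- r$extracted[[ei]]
      if (length(act$submaps) == 0L) return(NA_real_)
      rand_index(pred, act)
    }, 0)
  }
  r_spec <- score(function(r)
    if (length(unique(r$td$labels)) > 1L)
      fit_gda_metric(r$td$dx, r$td$labels, lambda = shrinkage) else NULL)
  general_metric <- fit_gda_metric(gen_dx, gen_y, lambda = shrinkage)
  r_gen <- score(function(r) general_metric)
  summarize <- function(r) list(exact = mean(r == 1, na.rm = TRUE),
                                mean_rand = mean(r, na.rm = TRUE),
                                n = sum(!is.na(r)), rand = r)
  list(specific = summarize(r_spec), general = summarize(r_gen),
       chance = chance_accuracy(5, 2))
}

#' Linear-metric weight recovery study
#'
#' For each synthetic subject, generates pairwise-contrast environments
#' (two active features per environment, so structures adjudicate feature
#' pairs), derives the true structures, fits a linear metric by DIRECT
#' global optimization, and correlates the learned weight profile -- mapped
#' back to the raw feature scale -- with the subject's true weights.
#'
#' @param n_subjects,n_envs study size.
#' @param budget DIRECT objective-evaluation budget per subject.
#' @param seed master seed.
#' @param sparsity subject weight sparsity.
#' @return list with `spearman` (per subject) and `median`.
#' @export
run_weight_recovery <- function(n_subjects = 50L, n_envs = 20L,
                                budget = 150L, seed = 1L, sparsity = 1.5) {
  base <- as.integer(seed) %% 1000000L
  rho <- vapply(seq_len(n_subjects), function(si) {
    subj <- make_subject(base + si * 13L, sparsity = sparsity)
    envs <- lapply(seq_len(n_envs), function(e)
      make_environment(base + si * 1000L + e, layout = "contrastive",
                       n_active = 2L))
    structs <- lapply(seq_along(envs), function(e)
      true_structure(subj, envs[[e]], seed = base + e))
    ok <- vapply(structs, function(m) length(m$submaps) > 0L, TRUE)
    if (sum(ok) < 2L) return(NA_real_)
    met <- fit_linear_metric(structs[ok], lapply(envs[ok], `[[`, "table"),
                             budget = budget, seed = si)
    w_raw <- met$weights / met$scale^2   # back to the raw feature scale
    suppressWarnings(stats::cor(w_raw, subj$weights, method = "spearman"))
  }, 0)
  list(spearman = rho, median = stats::median(rho, na.rm = TRUE))
}
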