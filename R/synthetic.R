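#' Synthetic subjects and environments
#'
#' The simulator stands in for human participants: each synthetic subject
#' owns a true psychological space (a sparse non-negative weighting of the
#' features, or a nonlinear grouping rule), recall noise (the probability of
#' a distraction swap in a trial) and sketch noise. Environments are either
#' the controlled training layout -- two groups of two buildings with equal
#' colour and function within a group, plus a variable middle building -- or
#' fully random layouts. Ground-truth structures are the clusterings the
#' subject's true space induces; recall sequences list sub-maps contiguously
#' with occasional injected cross-sub-map swaps; sketch maps are noisy,
#' optionally sub-map-contracted, similarity-transformed copies of the true
#' positions.
#'
#' @name synthetic_subjects
NULL

synthetic_feature_names <- function()
  c("spatial", "visual", "functional", "phonetic", "morphological")

#' Create a synthetic subject
#'
#' Feature weights are drawn from a symmetric Dirichlet whose concentration
#' is the reciprocal of `sparsity`, so larger sparsity concentrates weight
#' on fewer features (matching the large between-subject variability in
#' feature importances) and sparsity near 0 gives near-uniform weights.
#'
#' @param seed integer seed (same seed, same subject).
#' @param features character vector of feature names the subject weighs.
#' @param sparsity Dirichlet sparsity (>= 0, default 0.5).
#' @param swap_prob probability of one distraction swap per recall trial.
#' @param sketch_sigma standard deviation of sketch-map position noise, in
#'   units of the environment extent.
#' @param contraction within-sub-map contraction factor of sketch distances
#'   (1 = none).
#' @param rule `"linear"` (weighted features) or `"quadratic"` (grouping
#'   driven by a nonmonotone, variance-based visual rule).
#' @return object of class `synthetic_subject`.
#' @export
make_subject <- function(seed, features = synthetic_feature_names(),
                         sparsity = 0.5, swap_prob = 0,
                         sketch_sigma = 0.05, contraction = 1,
                         rule = c("linear", "quadratic")) {
  rule <- match.arg(rule)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  conc <- 1 / max(sparsity, 1e-6)
  g <- stats::rgamma(length(features), shape = conc)
  if (all(g == 0)) g <- rep(1, length(features))
  w <- g / sum(g)
  names(w) <- features
  structure(list(weights = w, swap_prob = swap_prob,
                 sketch_sigma = sketch_sigma, contraction = contraction,
                 rule = rule, seed = seed),
            class = "synthetic_subject")
}

#' Create a synthetic environment
#'
#' `"two-groups-middle"` builds the controlled 5-building training layout:
#' two spatially tight groups of two buildings, equal colour and function
#' within each group (one group shops, one houses), and a middle building
#' with freely varied parameters. `"random"` places `n_buildings` uniformly
#' with unconstrained colours and functions. Pairwise dissimilarities
#' (visual, functional, and phonetic/morphological name-similarity
#' surrogates) are derived from per-building latent attributes plus rating
#' noise; spatial distance is the exact Euclidean distance.
#'
#' @param seed integer seed.
#' @param layout `"two-groups-middle"`, `"random"`, or `"contrastive"`.
#'   The contrastive layout gives every feature its own latent two-group
#'   split (tight within-group values, wide between), so different features
#'   suggest different partitions and a subject's feature weighting is
#'   identifiable from the structures it induces -- the same rationale as
#'   generating controlled environments to probe feature importances.
#' @param n_buildings number of buildings (exactly 5 for the controlled
#'   layout; >= 2 otherwise).
#' @param group_sep distance between group centers (controlled layout).
#' @param within_sd spatial spread inside a group.
#' @param sim_noise sd of the rating noise added to the derived pairwise
#'   dissimilarities (0 makes the table an exact function of the latent
#'   attributes).
#' @param middle optional named list overriding the middle building's
#'   parameters (`frac` along the group axis, `colour`, `func`).
#' @param n_active number of features carrying a latent split in the
#'   contrastive layout (default 2).
#' @return object of class `synthetic_environment` with per-building
#'   `features` (matrix with a `feature_of` attribute) and a pairwise
#'   [feature_table()].
#' @export
make_environment <- function(seed, layout = c("two-groups-middle", "random",
                                              "contrastive"),
                             n_buildings = 5L, group_sep = 10,
                             within_sd = 0.6, sim_noise = 0,
                             middle = NULL, n_active = 2L) {
  layout <- match.arg(layout)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (layout == "contrastive") {
    if (n_buildings < 4L) stop("need at least 4 buildings")
    ids <- sprintf("b%02d", seq_len(n_buildings))
    ## n_active randomly chosen features carry a latent two-group split;
    ## the rest stay flat, so environments pit features against each other
    active <- sample(synthetic_feature_names(), n_active)
    two_split <- function() {
      g <- stats::rbinom(n_buildings, 1L, 0.5)
      while (min(tabulate(g + 1L, 2L)) < 2L && n_buildings >= 4L)
        g <- stats::rbinom(n_buildings, 1L, 0.5)
      g
    }
    binval <- function(on) {
      if (!on) return(stats::runif(1, 0, 10) +
                        stats::rnorm(n_buildings, sd = 0.3))
      c(1.5, 8.5)[two_split() + 1L] + stats::rnorm(n_buildings, sd = 0.3)
    }
    if ("spatial" %in% active) {
      ctr <- rbind(c(0, 0), c(group_sep, 0))[two_split() + 1L, ]
      pos <- ctr + matrix(stats::rnorm(2L * n_buildings, sd = within_sd),
                          ncol = 2L)
    } else {
      pos <- matrix(stats::rnorm(2L * n_buildings, sd = within_sd),
                    ncol = 2L)
    }
    colour <- binval("visual" %in% active)
    func <- if ("functional" %in% active) two_split()
            else stats::rbinom(1L, 1L, 0.5) + integer(n_buildings)
    groups <- NULL; middle_id <- NULL
    phon_bin <- binval("phonetic" %in% active)
    morph_bin <- binval("morphological" %in% active)
  } else if (layout == "two-groups-middle") {
    if (n_buildings != 5L)
      stop("the two-groups-middle layout uses exactly 5 buildings")
    ids <- sprintf("b%02d", 1:5)
    c1 <- c(0, 0); c2 <- c(group_sep, 0)
    pos <- rbind(
      c1 + stats::rnorm(2, sd = within_sd),
      c1 + stats::rnorm(2, sd = within_sd),
      c2 + stats::rnorm(2, sd = within_sd),
      c2 + stats::rnorm(2, sd = within_sd),
      c(0, 0))
    frac <- if (!is.null(middle$frac)) middle$frac else stats::runif(1, 0.25, 0.75)
    pos[5L, ] <- c1 + frac * (c2 - c1) +
      stats::rnorm(2, sd = within_sd)
    colour_g1 <- stats::runif(1, 0, 10)
    colour_g2 <- stats::runif(1, 0, 10)
    colour <- c(colour_g1, colour_g1, colour_g2, colour_g2,
                if (!is.null(middle$colour)) middle$colour
                else stats::runif(1, 0, 10))
    func <- c(1, 1, 0, 0,
              if (!is.null(middle$func)) middle$func
              else stats::rbinom(1, 1, 0.5))
    groups <- list(ids[1:2], ids[3:4])
    middle_id <- ids[5L]
  } else {
    if (n_buildings < 2L) stop("need at least 2 buildings")
    ids <- sprintf("b%02d", seq_len(n_buildings))
    pos <- cbind(stats::runif(n_buildings, 0, 10),
                 stats::runif(n_buildings, 0, 10))
    colour <- stats::runif(n_buildings, 0, 10)
    func <- stats::rbinom(n_buildings, 1, 0.5)
    if (length(unique(func)) == 1L) func[1L] <- 1 - func[1L]
    groups <- NULL
    middle_id <- NULL
  }
  if (layout == "contrastive") {
    phon <- phon_bin; morph <- morph_bin
  } else {
    phon <- stats::runif(length(ids), 0, 10)
    morph <- stats::runif(length(ids), 0, 10)
  }
  rownames(pos) <- ids

  features <- cbind(spatial.x = pos[, 1L], spatial.y = pos[, 2L],
                    visual = colour, functional = 9 * func,
                    phonetic = phon, morphological = morph)
  rownames(features) <- ids
  attr(features, "feature_of") <- c("spatial", "spatial", "visual",
                                    "functional", "phonetic",
                                    "morphological")

  n <- length(ids)
  pr <- t(utils::combn(ids, 2L))
  noisy <- function(x) pmax(x + stats::rnorm(length(x), sd = sim_noise), 0)
  d_of <- function(col) {
    a <- match(pr[, 1L], ids); b <- match(pr[, 2L], ids)
    abs(col[a] - col[b])
  }
  a <- match(pr[, 1L], ids); b <- match(pr[, 2L], ids)
  diffs <- cbind(
    spatial = sqrt((pos[a, 1L] - pos[b, 1L])^2 + (pos[a, 2L] - pos[b, 2L])^2),
    visual = noisy(d_of(colour)),
    functional = noisy(d_of(9 * func)),
    phonetic = noisy(d_of(phon)),
    morphological = noisy(d_of(morph)))

  structure(list(id = paste0("env", seed), layout = layout, buildings = ids,
                 positions = pos,
                 attrs = data.frame(colour = colour, func = func,
                                    phonetic = phon, morphological = morph,
                                    row.names = ids),
                 features = features,
                 table = feature_table(pr, diffs),
                 groups = groups, middle = middle_id, seed = seed),
            class = "synthetic_environment")
}

## The subject's true metric lives on raw feature scales: all synthetic
## features are constructed on commensurate 0-10 scales, so the weights are
## directly the feature importances (standardization is a fitting device,
## not part of the subject).
true_metric_for <- function(subject, environment) {
  linear_metric(pmax(subject$weights, 1e-9))
}

#' Ground-truth structure of an environment for a subject
#'
#' The structure the subject's true psychological space induces: buildings
#' are embedded with the subject's true feature weights and clustered with
#' the same DP-GMM used for prediction. Clusters of one building become
#' excluded singletons, mirroring how single-object sub-maps are excluded
#' from subject data. For the controlled layout this reduces to assigning
#' the middle building to its nearest group whenever the groups are well
#' separated.
#'
#' @param subject a [make_subject()] subject.
#' @param environment a [make_environment()] environment.
#' @param seed integer seed for the clustering.
#' @param alpha1,truncation DP-GMM settings.
#' @return a [map_structure()].
#' @export
true_structure <- function(subject, environment, seed = 1L, alpha1 = 1.0,
                           truncation = 10L) {
  metric <- true_metric_for(subject, environment)
  feats <- environment$features
  if (subject$rule == "quadratic") {
    ## nonmonotone visual perception: colours equidistant from the scale
    ## midpoint look alike to this subject
    feats[, "visual"] <- (feats[, "visual"] - 5)^2 / 5
  }
  pts <- embed_linear(feats, metric,
                      feature_of = attr(environment$features, "feature_of"))
  if (max(stats::dist(pts)) < 1e-12)
    return(map_structure(submaps = list(environment$buildings)))
  model <- fit_dpgmm(pts, alpha1 = alpha1, truncation = truncation,
                     seed = seed)
  z <- assign_clusters(model, pts)
  groups <- split(names(z), z)
  sizes <- vapply(groups, length, 1L)
  map_structure(submaps = unname(groups[sizes >= 2L]),
                excluded = unlist(unname(groups[sizes == 1L])))
}

#' Generate a recall trial from a known structure
#'
#' Each sequence lists the structure's groups (sub-maps plus each excluded
#' singleton) contiguously: random group order and random within-group
#' order; in cued sequences the cue building's group comes first with the
#' cue building first inside it. By default every building is cued once and
#' two uncued sequences are appended. With probability `swap_prob` a single
#' adjacent transposition across a group boundary is injected into one
#' sequence of the trial (never displacing a cue), emulating a distraction.
#'
#' @param structure a [map_structure()] covering the environment.
#' @param n_cued number of cued sequences (default: one per building).
#' @param n_uncued number of uncued sequences (default 2).
#' @param swap_prob probability of injecting one swap into the trial.
#' @param seed integer seed.
#' @param environment_id carried into the returned trial.
#' @param verify resample the clean trial's orderings (up to `max_tries`
#'   times) until tree analysis inverts it exactly. Randomly drawn orders
#'   can by chance keep a spurious subset (e.g. a pair inside a larger
#'   sub-map) contiguous in every sequence; verified resampling guarantees
#'   the order variety that cueing is meant to produce. Structures with
#'   fewer than 2 groups are inherently unidentifiable from recall order and
#'   are returned unverified.
#' @param max_tries resampling attempts before giving up.
#' @return a [recall_trial()]; attribute `corrupted` is the index of the
#'   corrupted sequence, or 0.
#' @export
generate_recall_sequences <- function(structure, n_cued = NULL,
                                      n_uncued = 2L, swap_prob = 0,
                                      seed = 1L, environment_id = "env",
                                      verify = TRUE, max_tries = 50L) {
  if (swap_prob < 0 || swap_prob > 1) stop("swap_prob must be in [0, 1]")
  groups <- c(structure$submaps, as.list(structure$excluded))
  if (!length(groups)) stop("structure is empty")
  buildings <- sort(unlist(groups))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(n_cued)) n_cued <- length(buildings)

  group_of <- integer(length(buildings)); names(group_of) <- buildings
  for (k in seq_along(groups)) group_of[groups[[k]]] <- k

  one_seq <- function(cue) {
    ord_groups <- sample(seq_along(groups))
    if (!is.na(cue)) {
      gk <- group_of[[cue]]
      ord_groups <- c(gk, setdiff(ord_groups, gk))
    }
    out <- c()
    for (k in ord_groups) {
      g <- groups[[k]]
      g <- if (length(g) > 1L) sample(g) else g
      if (!is.na(cue) && group_of[[cue]] == k)
        g <- c(cue, setdiff(g, cue))
      out <- c(out, g)
    }
    out
  }

  draw_trial <- function() {
    cues <- rep_len(sample(buildings), n_cued)
    c(lapply(cues, one_seq),
      lapply(seq_len(n_uncued), function(i) one_seq(NA)))
  }
  cued <- c(rep(TRUE, n_cued), rep(FALSE, n_uncued))

  inverts <- function(seqs) {
    tr <- recall_trial(lapply(seq_along(seqs), function(i)
      recall_sequence(seqs[[i]], cued = cued[i],
                      cue_id = if (cued[i]) seqs[[i]][1L] else NULL)))
    got <- extract_submaps(build_ordered_tree(
      resolve_laminar(find_consistent_subsets(tr)), buildings))
    structures_equal(got, structure)
  }

  seqs <- draw_trial()
  if (verify && length(groups) >= 2L) {
    tries <- 1L
    while (!inverts(seqs) && tries < max_tries) {
      seqs <- draw_trial()
      tries <- tries + 1L
    }
  }

  corrupted <- 0L
  if (stats::runif(1) < swap_prob && length(groups) >= 2L) {
    for (try_idx in sample(seq_along(seqs))) {
      s <- seqs[[try_idx]]
      bnd <- which(group_of[s[-length(s)]] != group_of[s[-1L]])
      if (cued[try_idx]) bnd <- bnd[bnd > 1L]  # never displace the cue
      if (length(bnd)) {
        j <- if (length(bnd) == 1L) bnd else sample(bnd, 1L)
        s[c(j, j + 1L)] <- s[c(j + 1L, j)]
        seqs[[try_idx]] <- s
        corrupted <- try_idx
        break
      }
    }
  }

  trial <- recall_trial(lapply(seq_along(seqs), function(i)
    recall_sequence(seqs[[i]], cued = cued[i],
                    cue_id = if (cued[i]) seqs[[i]][1L] else NULL)),
    environment_id = environment_id)
  attr(trial, "corrupted") <- corrupted
  trial
}

#' Generate a noisy sketch map
#'
#' True positions distorted by a hierarchical noise model: when a structure
#' is supplied, each sub-map is treated as a local reference frame -- its
#' centroid is jittered with the full noise sd (`sketch_sigma` times the
#' environment extent) while buildings inside the frame receive only half
#' that jitter, so within-sub-map relations are remembered more precisely
#' than across-sub-map relations. Within-sub-map distances are additionally
#' contracted toward the centroid by the subject's contraction factor.
#' Finally a random similarity transform (rotation, scale, translation)
#' emulates the uncued empty canvas. Without a structure the noise is plain
#' i.i.d.
#'
#' @param environment a [make_environment()] environment.
#' @param subject a [make_subject()] subject (supplies `sketch_sigma` and
#'   `contraction`).
#' @param seed integer seed.
#' @param structure optional [map_structure()] supplying the local frames.
#' @return matrix of sketch coordinates (rows = buildings).
#' @export
generate_sketch_map <- function(environment, subject, seed = 1L,
                                structure = NULL) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  P <- environment$positions
  extent <- max(apply(P, 2L, function(x) diff(range(x))), 1e-9)
  sig <- subject$sketch_sigma * extent
  if (!is.null(structure) && length(structure$submaps)) {
    framed <- unlist(structure$submaps)
    for (sm in structure$submaps) {
      ctr <- colMeans(P[sm, , drop = FALSE])
      P[sm, ] <- sweep(sweep(P[sm, , drop = FALSE], 2L, ctr) *
                         subject$contraction, 2L, ctr, "+")
      ## coherent frame jitter plus reduced within-frame jitter
      P[sm, ] <- P[sm, ] +
        matrix(stats::rnorm(2L, sd = sig), length(sm), 2L, byrow = TRUE) +
        matrix(stats::rnorm(2L * length(sm), sd = sig / 2), ncol = 2L)
    }
    loose <- setdiff(rownames(P), framed)
    if (length(loose))
      P[loose, ] <- P[loose, , drop = FALSE] +
        matrix(stats::rnorm(2L * length(loose), sd = sig * sqrt(1.25)),
               ncol = 2L)
  } else {
    P <- P + matrix(stats::rnorm(length(P), sd = sig), ncol = 2L)
  }
  theta <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  s <- stats::runif(1, 0.5, 2)
  shift <- stats::runif(2, -5, 5)
  out <- s * P %*% R + matrix(shift, nrow(P), 2L, byrow = TRUE)
  rownames(out) <- rownames(environment$positions)
  out
}

#' Simulate a cohort of subjects with environments and ground truth
#'
#' Convenience generator used by the analysis drivers and benchmarks: for
#' each subject, draws environments, derives the true structures, recall
#' trials and sketch maps. A pure function of its configuration and seed.
#'
#' @param n_subjects,n_envs cohort size.
#' @param seed master integer seed.
#' @param layout,n_buildings,sim_noise passed to [make_environment()].
#' @param sparsity,swap_prob,sketch_sigma,contraction,rule passed to
#'   [make_subject()].
#' @return list of subjects; each element carries `subject`,
#'   `environments`, `structures` (ground truth) and `trials`.
#' @export
simulate_cohort <- function(n_subjects, n_envs, seed = 1L,
                            layout = "random", n_buildings = 5L,
                            sim_noise = 0, sparsity = 0.5, swap_prob = 0,
                            sketch_sigma = 0.05, contraction = 1,
                            rule = "linear", n_active = 2L) {
  base <- as.integer(seed) %% 1000000L
  lapply(seq_len(n_subjects), function(si) {
    subj <- make_subject(base + si * 7919L, sparsity = sparsity,
                         swap_prob = swap_prob,
                         sketch_sigma = sketch_sigma,
                         contraction = contraction, rule = rule)
    envs <- lapply(seq_len(n_envs), function(ei)
      make_environment(base + si * 104729L + ei, layout = layout,
                       n_buildings = n_buildings, sim_noise = sim_noise,
                       n_active = n_active))
    structures <- lapply(seq_along(envs), function(ei)
      true_structure(subj, envs[[ei]], seed = base + ei))
    trials <- lapply(seq_along(envs), function(ei)
      generate_recall_sequences(structures[[ei]],
                                swap_prob = subj$swap_prob,
                                seed = base + si * 31L + ei,
                                environment_id = envs[[ei]]$id))
    list(subject = subj, environments = envs, structures = structures,
         trials = trials)
  })
}
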