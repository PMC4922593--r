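#' Recall sequences, trials and map structures
#'
#' A recall sequence is one complete recall of all buildings in an
#' environment, possibly cued (in which case the cue building is recalled
#' first). A recall trial bundles the sequences a subject produced for one
#' environment. A map structure is the object the whole analysis revolves
#' around: a partition of buildings into sub-maps (sets of size >= 2 that are
#' recalled contiguously in every sequence) plus excluded singletons.
#'
#' @param ordering character vector of building IDs, a permutation of the
#'   environment's building set.
#' @param cued logical; was the first building given as a cue?
#' @param cue_id building ID of the cue (required when `cued` is TRUE).
#' @return `recall_sequence()` returns an object of class `recall_sequence`.
#' @export
recall_sequence <- function(ordering, cued = FALSE, cue_id = NULL) {
  ordering <- as.character(ordering)
  if (anyDuplicated(ordering))
    stop("ordering must contain each building exactly once")
  if (cued) {
    if (is.null(cue_id)) cue_id <- ordering[1L]
    if (!identical(as.character(cue_id), ordering[1L]))
      stop("cued sequence must start with its cue building")
  } else {
    cue_id <- NA_character_
  }
  structure(list(ordering = ordering, cued = isTRUE(cued),
                 cue_id = as.character(cue_id)),
            class = "recall_sequence")
}

#' @param sequences list of `recall_sequence` objects over the same building
#'   set.
#' @param environment_id identifier of the environment the trial belongs to.
#' @return `recall_trial()` returns an object of class `recall_trial`.
#' @rdname recall_sequence
#' @export
recall_trial <- function(sequences, environment_id = "env") {
  if (length(sequences) == 0L) stop("trial contains no recall sequences")
  sequences <- lapply(sequences, function(s) {
    if (inherits(s, "recall_sequence")) s else recall_sequence(s)
  })
  ref <- sort(sequences[[1L]]$ordering)
  for (s in sequences)
    if (!identical(sort(s$ordering), ref))
      stop("all sequences in a trial must be permutations of the same building set")
  structure(list(environment_id = environment_id, sequences = sequences,
                 buildings = ref),
            class = "recall_trial")
}

#' @param submaps list of character vectors, each a sub-map of >= 2 building
#'   IDs; mutually disjoint.
#' @param excluded character vector of building IDs excluded as singletons.
#' @param singleton_clusters optional list of single-building clusters a
#'   prediction produced (kept separate because predicted singletons are
#'   scored as mistakes rather than excluded).
#' @return `map_structure()` returns an object of class `map_structure`.
#' @rdname recall_sequence
#' @export
map_structure <- function(submaps = list(), excluded = character(),
                          singleton_clusters = list()) {
  submaps <- lapply(submaps, function(s) sort(as.character(s)))
  if (any(vapply(submaps, length, 1L) < 2L))
    stop("sub-maps must contain at least two buildings")
  all_ids <- unlist(submaps)
  if (anyDuplicated(all_ids)) stop("sub-maps must be disjoint")
  excluded <- sort(as.character(excluded))
  if (length(intersect(all_ids, excluded)))
    stop("excluded singletons cannot also appear in a sub-map")
  ord <- order(vapply(submaps, function(s) s[1L], ""))
  structure(list(submaps = submaps[ord], excluded = excluded,
                 singleton_clusters = lapply(singleton_clusters, as.character)),
            class = "map_structure")
}

#' @export
print.map_structure <- function(x, ...) {
  cat("Map structure:", length(x$submaps), "sub-map(s)\n")
  for (s in x$submaps) cat("  {", paste(s, collapse = ", "), "}\n")
  if (length(x$excluded))
    cat("  excluded singletons:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Test two map structures for equality
#'
#' Structures are equal when they contain the same sub-maps (as sets) and the
#' same excluded singletons.
#'
#' @param a,b `map_structure` objects.
#' @return logical scalar.
#' @export
structures_equal <- function(a, b) {
  key <- function(m) {
    sm <- sort(vapply(m$submaps, paste, "", collapse = "\r"))
    paste(c(sm, "|", m$excluded), collapse = "\n")
  }
  identical(key(a), key(b))
}

## All buildings referenced by a structure (sub-maps + excluded).
structure_buildings <- function(m)
  sort(c(unlist(m$submaps), m$excluded,
         unlist(m$singleton_clusters)))

## Membership vector over `buildings`: sub-map index, or a unique negative
## code per singleton so that every singleton forms its own group.
structure_membership <- function(m, buildings) {
  z <- integer(length(buildings))
  names(z) <- buildings
  for (k in seq_along(m$submaps))
    z[intersect(m$submaps[[k]], buildings)] <- k
  single <- buildings[!(buildings %in% unlist(m$submaps))]
  z[single] <- -seq_along(single)
  z
}

## Analysed part of one sequence: the cued first element is dropped when
## exclude_cue_position is set, so only uncued recall order is used.
analysed_ordering <- function(s, exclude_cue_position) {
  if (exclude_cue_position && isTRUE(s$cued)) s$ordering[-1L] else s$ordering
}

## Is the subset `members` contiguous (in any internal order) in `ordering`,
## counting only the members actually present in `ordering`?
is_contiguous <- function(members, ordering) {
  p <- match(members, ordering)
  p <- p[!is.na(p)]
  length(p) <= 1L || (max(p) - min(p) + 1L) == length(p)
}

#' Find subsets consistently recalled together
#'
#' Enumerates every subset of buildings (of size >= 2 and smaller than the
#' full set) that occurs as a contiguous block, in any internal order, in
#' every recall sequence of the trial. These consistent subsets are the raw
#' material of the ordered-tree analysis: buildings always recalled together
#' are taken to live on the same sub-map.
#'
#' When `exclude_cue_position` is `TRUE` (the default) the cued first element
#' of each cued sequence is dropped before the contiguity test, so that only
#' the uncued part of the sequence is analysed; a subset containing a dropped
#' cue is required to be contiguous among its remaining members.
#'
#' @param trial a [recall_trial()].
#' @param exclude_cue_position drop the cued first element of cued sequences
#'   before the contiguity test.
#' @return list of character vectors (sorted building IDs), one per
#'   consistent subset.
#' @export
find_consistent_subsets <- function(trial, exclude_cue_position = TRUE) {
  stopifnot(inherits(trial, "recall_trial"))
  buildings <- trial$buildings
  B <- length(buildings)
  if (B < 3L) return(list())
  seqs <- lapply(trial$sequences, analysed_ordering,
                 exclude_cue_position = exclude_cue_position)

  ## Candidate subsets: contiguous blocks of the first sequence; if that
  ## sequence was truncated by cue exclusion, every block may additionally be
  ## augmented with the dropped cue (whose position is unconstrained there).
  first <- seqs[[1L]]
  dropped <- setdiff(buildings, first)
  cand <- list()
  n1 <- length(first)
  for (i in seq_len(n1)) {
    for (j in i:n1) {
      block <- first[i:j]
      if (length(block) >= 2L) cand[[length(cand) + 1L]] <- block
      if (length(dropped) && length(block) >= 1L)
        cand[[length(cand) + 1L]] <- c(block, dropped)
    }
  }
  cand <- lapply(cand, sort)
  cand <- cand[!duplicated(vapply(cand, paste, "", collapse = "\r"))]
  cand <- cand[vapply(cand, length, 1L) < B]

  keep <- vapply(cand, function(members) {
    for (s in seqs) if (!is_contiguous(members, s)) return(FALSE)
    TRUE
  }, TRUE)
  cand[keep]
}

## With few sequences, or when cue positions are dropped, two consistent
## subsets can partially overlap (typically a genuine sub-map against a
## near-complement artifact only contiguous because its missing member was
## a dropped cue). The tree pipeline resolves such conflicts
## deterministically by keeping a laminar family, preferring smaller
## subsets -- the elementary sub-maps. For well-varied full sequences the
## family is already laminar and this is a no-op.
resolve_laminar <- function(subsets) {
  ord <- order(vapply(subsets, length, 1L),
               vapply(subsets, paste, "", collapse = "\r"))
  lam <- list()
  for (s in subsets[ord]) {
    ok <- all(vapply(lam, function(t) {
      st <- intersect(s, t)
      length(st) == 0L || setequal(st, s) || setequal(st, t)
    }, TRUE))
    if (ok) lam[[length(lam) + 1L]] <- s
  }
  lam
}

#' Build the ordered tree of consistent subsets
#'
#' Nests the consistent subsets by set containment under a root covering the
#' full building set. Buildings not inside any consistent subset become
#' singleton leaf children of their smallest containing node. Genuine
#' contiguity-consistent subsets are always laminar (never partially
#' overlapping); a violation indicates corrupted input and raises an error
#' naming the offending pair.
#'
#' @param subsets list of character vectors as returned by
#'   [find_consistent_subsets()].
#' @param building_set character vector of all building IDs.
#' @return an object of class `ordered_tree` (nested lists with fields
#'   `members` and `children`; leaves have empty `children`).
#' @export
build_ordered_tree <- function(subsets, building_set) {
  building_set <- sort(as.character(building_set))
  subsets <- lapply(subsets, function(s) sort(as.character(s)))
  subsets <- subsets[!duplicated(vapply(subsets, paste, "", collapse = "\r"))]
  ## a subset equal to the root merges with the root
  subsets <- subsets[!vapply(subsets, identical, TRUE, y = building_set)]

  for (i in seq_along(subsets)) {
    for (j in seq_len(i - 1L)) {
      a <- subsets[[i]]; b <- subsets[[j]]
      ab <- intersect(a, b)
      if (length(ab) && !setequal(ab, a) && !setequal(ab, b))
        stop(sprintf("subsets {%s} and {%s} partially overlap (not laminar)",
                     paste(a, collapse = ","), paste(b, collapse = ",")))
    }
  }

  grow <- function(members, pool) {
    if (length(members) == 1L)
      return(list(members = members, children = list()))
    inside <- pool[vapply(pool, function(s) all(s %in% members), TRUE)]
    ## maximal subsets strictly inside `members` become child nodes
    maximal <- inside[vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j) {
        j != i && length(inside[[j]]) > length(inside[[i]]) &&
          all(inside[[i]] %in% inside[[j]])
      }, TRUE))
    }, TRUE)]
    children <- lapply(maximal, function(s)
      grow(s, inside[vapply(inside, function(x)
        all(x %in% s) && length(x) < length(s), TRUE)]))
    covered <- unlist(maximal)
    for (b in setdiff(members, covered))
      children[[length(children) + 1L]] <- list(members = b, children = list())
    ord <- order(vapply(children, function(ch) ch$members[1L], ""))
    list(members = members, children = children[ord])
  }

  structure(grow(building_set, subsets), class = "ordered_tree")
}

#' Ordered-tree statistics
#'
#' `tree_height()` is the maximum number of edges from the root to any leaf.
#' `log_cardinality()` is the base-2 logarithm of the number of recall
#' sequences consistent with the tree, log2(prod n_i!) over the branch counts
#' n_i of all internal nodes.
#'
#' @param tree an `ordered_tree`.
#' @return a single number.
#' @export
tree_height <- function(tree) {
  h <- function(node) {
    if (!length(node$children)) return(0L)
    1L + max(vapply(node$children, h, 0L))
  }
  h(tree)
}

#' @rdname tree_height
#' @export
log_cardinality <- function(tree) {
  c2 <- function(node) {
    if (!length(node$children)) return(0)
    lfactorial(length(node$children)) / log(2) +
      sum(vapply(node$children, c2, 0))
  }
  c2(tree)
}

## Tree from a subset of sequences of a trial (helper for jackknifing).
tree_from_sequences <- function(trial, idx, exclude_cue_position = TRUE) {
  sub <- recall_trial(trial$sequences[idx], trial$environment_id)
  build_ordered_tree(
    resolve_laminar(
      find_consistent_subsets(sub,
                              exclude_cue_position = exclude_cue_position)),
    trial$buildings)
}

#' Jackknife removal of outlier recall sequences
#'
#' For each sequence i the tree T_i is computed from all sequences except i,
#' together with its height h(T_i) and log-cardinality c(T_i). Each statistic
#' is z-scored against the mean and population variance of the N
#' leave-one-out values; sequence i is removed when either |z| exceeds the
#' two-sided normal threshold for `alpha`. Removal is single-pass: all
#' flagged sequences are dropped together and the final tree is built from
#' the kept ones. A statistic with zero variance contributes z = 0, so
#' perfectly consistent trials lose nothing.
#'
#' @param trial a [recall_trial()] with at least 3 sequences.
#' @param alpha two-sided significance level (default 0.05).
#' @param exclude_cue_position see [find_consistent_subsets()].
#' @return list with elements `kept` (indices of retained sequences),
#'   `removed` (indices removed), `tree` (final `ordered_tree`), and the
#'   leave-one-out statistics `h`, `c`.
#' @export
jackknife_outliers <- function(trial, alpha = 0.05,
                               exclude_cue_position = TRUE) {
  stopifnot(inherits(trial, "recall_trial"))
  n <- length(trial$sequences)
  if (n < 3L) stop("jackknifing requires at least 3 recall sequences")

  h <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    ti <- tree_from_sequences(trial, setdiff(seq_len(n), i),
                              exclude_cue_position)
    h[i] <- tree_height(ti)
    cc[i] <- log_cardinality(ti)
  }
  zscore <- function(x) {
    v <- mean((x - mean(x))^2)  # population variance over the N omissions
    if (v == 0) rep(0, length(x)) else (x - mean(x)) / sqrt(v)
  }
  thr <- stats::qnorm(1 - alpha / 2)
  flagged <- abs(zscore(h)) > thr | abs(zscore(cc)) > thr
  if (all(flagged)) flagged[] <- FALSE  # degenerate: keep everything
  kept <- which(!flagged)
  tree <- tree_from_sequences(trial, kept, exclude_cue_position)
  list(kept = kept, removed = which(flagged), tree = tree, h = h, c = cc)
}

#' Extract elementary sub-maps from an ordered tree
#'
#' Elementary sub-maps are the internal nodes, below the root, all of whose
#' children are leaves -- the level just above the leaves, i.e. consistent
#' subsets not containing smaller consistent subsets. Buildings outside every
#' such node are excluded as singletons. A flat tree (no consistent subsets)
#' yields a structure with no sub-maps.
#'
#' @param tree an `ordered_tree`.
#' @return a [map_structure()].
#' @export
extract_submaps <- function(tree) {
  submaps <- list()
  walk <- function(node, is_root) {
    if (!length(node$children)) return(invisible())
    all_leaves <- all(vapply(node$children, function(ch)
      length(ch$children) == 0L, TRUE))
    if (all_leaves && !is_root && length(node$members) >= 2L) {
      submaps[[length(submaps) + 1L]] <<- node$members
    } else {
      for (ch in node$children) walk(ch, FALSE)
    }
  }
  walk(tree, TRUE)
  map_structure(submaps,
                excluded = setdiff(tree$members, unlist(submaps)))
}

#' Extract a map structure from a recall trial
#'
#' Convenience wrapper chaining [jackknife_outliers()] (optional),
#' [find_consistent_subsets()], [build_ordered_tree()] and
#' [extract_submaps()].
#'
#' @inheritParams jackknife_outliers
#' @param jackknife run jackknife outlier removal first (requires >= 3
#'   sequences).
#' @return a [map_structure()]; the indices of removed sequences are attached
#'   as attribute `removed`.
#' @export
extract_structure <- function(trial, alpha = 0.05, jackknife = TRUE,
                              exclude_cue_position = TRUE) {
  if (jackknife && length(trial$sequences) >= 3L) {
    jk <- jackknife_outliers(trial, alpha, exclude_cue_position)
    out <- extract_submaps(jk$tree)
    attr(out, "removed") <- jk$removed
  } else {
    tree <- build_ordered_tree(
      resolve_laminar(find_consistent_subsets(trial, exclude_cue_position)),
      trial$buildings)
    out <- extract_submaps(tree)
    attr(out, "removed") <- integer()
  }
  out
}

#' Detect circular recall protocols
#'
#' Returns `TRUE` when every sequence of the trial is a rotation of one
#' common cyclic ordering -- the signature of a subject re-reading a fixed
#' written list instead of recalling from memory. Reversals are not counted
#' as rotations.
#'
#' @param trial a [recall_trial()] with at least 2 sequences.
#' @return logical scalar.
#' @export
detect_circular <- function(trial) {
  stopifnot(inherits(trial, "recall_trial"))
  if (length(trial$sequences) < 2L)
    stop("circularity detection requires at least 2 sequences")
  ref <- trial$sequences[[1L]]$ordering
  n <- length(ref)
  doubled <- c(ref, ref)
  for (s in trial$sequences[-1L]) {
    o <- s$ordering
    start <- match(o[1L], ref)
    if (is.na(start) || !identical(doubled[start:(start + n - 1L)], o))
      return(FALSE)
  }
  TRUE
}
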